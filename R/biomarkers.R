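#' Standardize a feature matrix
#'
#' Centers and scales columns to zero mean, unit variance (population sd,
#' 1/n, matching the penalized-likelihood scaling); constant columns are
#' dropped.
#'
#' @param X numeric matrix (samples x features).
#' @return list: `X` standardized, `center`, `scale`, `kept` (column index).
#' @export
standardize_features <- function(X) {
  ctr <- colMeans(X)
  sc <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  kept <- which(sc > 0)
  Xs <- sweep(sweep(X[, kept, drop = FALSE], 2, ctr[kept]), 2, sc[kept], "/")
  list(X = Xs, center = ctr[kept], scale = sc[kept], kept = kept)
}

lasso_objective <- function(X, y, beta0, beta, lambda) {
  eta <- drop(beta0 + X %*% beta)
  # mean logistic deviance (negative log-likelihood / n) + L1 penalty
  mean(log1p(exp(eta)) - y * eta) + lambda * sum(abs(beta))
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# one IRLS + cyclic coordinate-descent solve at fixed lambda, warm start.
# Coordinate updates cycle over an active set only; candidates enter the
# active set through a vectorized Karush-Kuhn-Tucker violation screen, so
# the per-feature loop never touches the full feature set.
lasso_logistic_fit <- function(X, y, lambda, beta0, beta,
                               tol = 1e-7, max_outer = 50) {
  n <- nrow(X); p <- ncol(X)
  for (outer in seq_len(max_outer)) {
    eta <- drop(beta0 + X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-5)
    z <- eta + (y - mu) / w
    den <- colSums(w * X^2) / n
    r <- z - beta0 - drop(X %*% beta)
    active <- which(beta != 0)
    repeat {
      # converge coordinate descent on the current active set
      for (inner in seq_len(10000)) {
        delta <- 0
        for (j in active) {
          rj <- r + X[, j] * beta[j]
          num <- sum(w * X[, j] * rj) / n
          a <- abs(num) - lambda
          bj <- if (a > 0) sign(num) * a / den[j] else 0
          if (bj != beta[j]) {
            delta <- max(delta, abs(bj - beta[j]))
            r <- rj - X[, j] * bj
            beta[j] <- bj
          }
        }
        b0 <- sum(w * r) / sum(w) + beta0
        delta <- max(delta, abs(b0 - beta0))
        r <- r - (b0 - beta0)
        beta0 <- b0
        if (delta < tol) break
      }
      # KKT screen over all features (vectorized)
      g <- drop(crossprod(X, w * r)) / n
      violators <- which(abs(g) > lambda + 1e-12 & beta == 0)
      if (length(violators) == 0) break
      active <- union(active, violators)
    }
    eta_new <- drop(beta0 + X %*% beta)
    if (max(abs(eta_new - eta)) < tol) break
  }
  list(beta0 = beta0, beta = beta)
}

#' L1-penalized logistic regression path
#'
#' Fits the lasso-logistic regularization path by iteratively reweighted
#' least squares with cyclic coordinate descent on the quadratic
#' approximation, warm-starting each penalty from the previous solution.
#' The intercept is unpenalized. Convergence is declared when the largest
#' coefficient change in a sweep falls below `1e-7`.
#'
#' @param X numeric matrix (samples x features), standardized columns
#'   (use [standardize_features()]).
#' @param y binary response (0/1); castes coded soldier = 1 by convention.
#' @param lambdas decreasing penalty sequence; by default 50 values
#'   log-spaced from `lambda_max` (smallest penalty with all-zero
#'   coefficients) down to `0.01 * lambda_max`.
#' @param n_lambda,lambda_min_ratio path shape when `lambdas` is `NULL`.
#' @return object of class `lasso_path`: `lambdas`, `beta0` (vector),
#'   `beta` (features x lambdas matrix), `lambda_max`.
#' @export
lasso_logistic_path <- function(X, y, lambdas = NULL, n_lambda = 50,
                                lambda_min_ratio = 0.01) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (nrow(X) < 4) stop("need at least 4 samples")
  n <- nrow(X)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  if (is.null(lambdas))
    lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                       length.out = n_lambda))
  beta <- rep(0, ncol(X))
  beta0 <- stats::qlogis(mean(y))
  B <- matrix(0, ncol(X), length(lambdas))
  b0s <- numeric(length(lambdas))
  for (k in seq_along(lambdas)) {
    fit <- lasso_logistic_fit(X, y, lambdas[k], beta0, beta)
    beta0 <- fit$beta0; beta <- fit$beta
    B[, k] <- beta; b0s[k] <- beta0
  }
  rownames(B) <- colnames(X)
  structure(list(lambdas = lambdas, beta0 = b0s, beta = B,
                 lambda_max = lambda_max),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  nz <- colSums(x$beta != 0)
  cat("lasso_path:", nrow(x$beta), "features,", length(x$lambdas),
      "penalties; nonzero range", min(nz), "-", max(nz), "\n")
  invisible(x)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < 2) stop("a class has fewer than 2 samples")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated penalty selection
#'
#' k-fold cross-validation with caste-stratified folds; the selected
#' penalty minimizes mean held-out logistic deviance (`rule = "min"`), or
#' is the largest penalty within one standard error of the minimum
#' (`rule = "1se"`).
#'
#' @inheritParams lasso_logistic_path
#' @param k number of folds (default 10).
#' @param seed integer seed controlling fold assignment (required).
#' @param rule `"min"` (default) or `"1se"`.
#' @return list of class `lasso_cv`: `lambda` (selected), `lambdas`,
#'   `cv_mean`, `cv_se`, `fit` (full-data `lasso_path`), `selected`
#'   (nonzero feature names at the selected penalty), `rule`, `seed`.
#' @export
cv_select_lambda <- function(X, y, k = 10, seed, rule = c("min", "1se"),
                             n_lambda = 50, lambda_min_ratio = 0.01) {
  rule <- match.arg(rule)
  y <- as.numeric(y)
  if (k > nrow(X)) stop("k exceeds sample count")
  full <- lasso_logistic_path(X, y, n_lambda = n_lambda,
                              lambda_min_ratio = lambda_min_ratio)
  fold <- stratified_folds(y, k, seed)
  dev <- matrix(NA_real_, k, length(full$lambdas))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (length(unique(y[tr])) < 2) stop("fold with one class only")
    pf <- lasso_logistic_path(X[tr, , drop = FALSE], y[tr],
                              lambdas = full$lambdas)
    eta <- sweep(X[te, , drop = FALSE] %*% pf$beta, 2, pf$beta0, "+")
    dev[f, ] <- colMeans(log1p(exp(eta)) - y[te] * eta)
  }
  cv_mean <- colMeans(dev)
  cv_se <- apply(dev, 2, stats::sd) / sqrt(k)
  i_min <- which.min(cv_mean)
  i_sel <- if (rule == "min") i_min else
    min(which(cv_mean <= cv_mean[i_min] + cv_se[i_min]))
  lambda <- full$lambdas[i_sel]
  sel <- rownames(full$beta)[full$beta[, i_sel] != 0]
  structure(list(lambda = lambda, index = i_sel, lambdas = full$lambdas,
                 cv_mean = cv_mean, cv_se = cv_se, fit = full,
                 selected = sel, rule = rule, seed = seed),
            class = "lasso_cv")
}

#' @export
print.lasso_cv <- function(x, ...) {
  cat("lasso_cv: selected lambda =", signif(x$lambda, 4), "(rule", x$rule,
      ");", length(x$selected), "nonzero features\n")
  invisible(x)
}

#' Biomarker report
#'
#' Builds the biomarker summary table: one row per transcript with a
#' nonzero lasso coefficient at the selected penalty, joined with its
#' putative source, average worker and soldier TMM expression, and the
#' DET flag from the differential-abundance results. Positive coefficients
#' indicate soldier-biased transcripts (soldier coded 1), negative ones
#' worker-biased.
#'
#' @param cv a `lasso_cv` from [cv_select_lambda()].
#' @param tmm a `tmm_norm`.
#' @param calls optional `source_calls` (for the `source` column).
#' @param de optional `de_results` with status (for the `det` column).
#' @return data frame of class `biomarker_report` with columns
#'   `transcript`, `source`, `coefficient`, `avg_worker_tmm`,
#'   `avg_soldier_tmm`, `det`.
#' @export
report_biomarkers <- function(cv, tmm, calls = NULL, de = NULL) {
  ids <- cv$selected
  coefs <- cv$fit$beta[ids, cv$index]
  w <- tmm$caste == "worker"
  rep <- data.frame(
    transcript = ids,
    source = if (is.null(calls)) NA_character_ else
      calls$source[match(ids, calls$transcript)],
    coefficient = as.numeric(coefs),
    avg_worker_tmm = if (length(ids)) rowMeans(
      tmm$tmm[ids, w, drop = FALSE]) else numeric(0),
    avg_soldier_tmm = if (length(ids)) rowMeans(
      tmm$tmm[ids, !w, drop = FALSE]) else numeric(0),
    det = if (is.null(de)) NA else
      de$status[match(ids, de$transcript)] != "ns",
    stringsAsFactors = FALSE)
  rownames(rep) <- NULL
  class(rep) <- c("biomarker_report", "data.frame")
  rep
}

#' Summary checks on a biomarker table
#'
#' Computes the consistency summaries used on biomarker tables: how many
#' rows carry the DET flag, how many DET rows have a termite putative
#' source, and for how many rows the coefficient sign agrees with the
#' TMM group-mean direction (positive coefficient iff soldier mean
#' exceeds worker mean).
#'
#' @param report data frame with columns `coefficient`, `avg_worker_tmm`,
#'   `avg_soldier_tmm`, `det`, `source` (a `biomarker_report` or any
#'   table with those columns).
#' @return list: `n_rows`, `n_det`, `n_termite_det`, `n_sign_consistent`.
#' @export
summarize_biomarkers <- function(report) {
  det <- report$det %in% c(TRUE, "yes")
  sign_ok <- (report$coefficient > 0) ==
    (report$avg_soldier_tmm > report$avg_worker_tmm)
  list(n_rows = nrow(report),
       n_det = sum(det),
       n_termite_det = sum(det & report$source %in% "termite"),
       n_sign_consistent = sum(sign_ok))
}
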