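#' Moment-based per-transcript NB dispersion estimation
#'
#' Counts are scaled to a common effective library size, then for each
#' transcript the raw moment estimate
#' `phi = max(0, (s^2 - xbar) / xbar^2)` is computed (variance =
#' mu + phi * mu^2 parameterization) and shrunk 50% toward the mean raw
#' estimate of its abundance bin (20 bins by mean scaled count). Estimates
#' are floored at `1e-8`.
#'
#' @param counts a `count_matrix`.
#' @param factors optional `tmm_norm` (for effective library sizes);
#'   plain library sizes are used when `NULL`.
#' @param n_bins number of abundance bins for the shrinkage trend.
#' @return named numeric vector of dispersions, one per transcript.
#' @export
estimate_dispersion <- function(counts, factors = NULL, n_bins = 20) {
  m <- counts$counts
  eff <- if (is.null(factors)) colSums(m) else factors$effective_libsize
  scaled <- sweep(m, 2, eff / mean(eff), "/")
  xbar <- rowMeans(scaled)
  s2 <- apply(scaled, 1, stats::var)
  raw <- ifelse(xbar > 0, pmax(0, (s2 - xbar) / xbar^2), 0)
  bins <- cut(rank(xbar, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  trend <- tapply(raw, bins, mean)[as.character(bins)]
  phi <- 0.5 * raw + 0.5 * as.numeric(trend)
  phi <- pmax(phi, 1e-8, na.rm = TRUE)
  stats::setNames(phi, rownames(m))
}

# NB Wald test for one transcript: log-link GLM with fixed dispersion,
# offset log effective library size, design [intercept, caste].
nb_wald_one <- function(y, caste01, offset, phi) {
  fit <- tryCatch(
    suppressWarnings(stats::glm(y ~ caste01 + offset(offset),
                                family = MASS::negative.binomial(
                                  theta = 1 / phi),
                                control = list(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged)
    return(c(log2fc = 0, se = NA_real_, p = 1, converged = 0))
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 2 || !is.finite(sm[2, 2]) || sm[2, 2] <= 0)
    return(c(log2fc = 0, se = NA_real_, p = 1, converged = 0))
  beta <- sm[2, 1]; se <- sm[2, 2]
  z <- beta / se
  c(log2fc = beta / log(2), se = se / log(2),
    p = 2 * stats::pnorm(-abs(z)), converged = 1)
}

#' Negative-binomial Wald test of caste effect
#'
#' Per transcript, fits a log-link negative-binomial GLM with fixed
#' dispersion, design `[intercept, caste]` and offset
#' `log(effective library size)`, and tests the caste coefficient with a
#' two-sided Wald z test. The fold change is reported as log2 soldier
#' relative to worker. Non-converged fits get `p = 1` and a flag.
#'
#' @param counts a `count_matrix` (filtered).
#' @param factors a `tmm_norm` from [tmm_normalize()] (or `NULL` to use
#'   raw library sizes).
#' @param phi named dispersion vector from [estimate_dispersion()]; when
#'   `NULL` it is estimated here.
#' @return data frame of class `de_results`: `transcript`, `log2fc`, `se`,
#'   `p`, `q`, `status` (filled by [call_dets()]; `NA` here), `converged`.
#' @export
nb_wald_test <- function(counts, factors = NULL, phi = NULL) {
  m <- counts$counts
  caste01 <- as.integer(counts$caste == "soldier")
  if (sum(caste01 == 0) < 2 || sum(caste01 == 1) < 2)
    stop("each caste needs at least 2 samples")
  eff <- if (is.null(factors)) colSums(m) else factors$effective_libsize
  if (is.null(phi)) phi <- estimate_dispersion(counts, factors)
  off <- log(eff)
  res <- t(vapply(seq_len(nrow(m)), function(g)
    nb_wald_one(m[g, ], caste01, off, phi[g]), numeric(4)))
  out <- data.frame(transcript = rownames(m),
                    log2fc = res[, "log2fc"], se = res[, "se"],
                    p = res[, "p"], q = NA_real_, status = NA_character_,
                    converged = res[, "converged"] == 1,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_results", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{k >= i}
#' (m * p_(k) / k)`, clipped to 1, mapped back to input order. Delegates to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Call differentially expressed transcripts
#'
#' The DET rule: soldier-biased iff `log2fc > log2(fc)` and `q < alpha`;
#' worker-biased iff `log2fc < -log2(fc)` and `q < alpha`; all thresholds
#' strict. With the defaults this is fold change > 2 or < 0.5 at
#' BH-adjusted p < 0.05.
#'
#' @param results a `de_results` data frame (q may be `NA`; it is
#'   (re)computed here with [bh_adjust()]).
#' @param fc fold-change threshold (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param calls optional `source_calls` to join a `source` column.
#' @return `de_results` with `q` and `status` filled
#'   (`"soldier-biased"`, `"worker-biased"` or `"ns"`); attribute
#'   `"det_counts"` holds the per-status tally.
#' @export
call_dets <- function(results, fc = 2.0, alpha = 0.05, calls = NULL) {
  lfc_cut <- log2(fc)
  results$q <- bh_adjust(results$p)
  results$status <- ifelse(results$log2fc > lfc_cut & results$q < alpha,
                           "soldier-biased",
                    ifelse(results$log2fc < -lfc_cut & results$q < alpha,
                           "worker-biased", "ns"))
  if (!is.null(calls))
    results$source <- calls$source[match(results$transcript,
                                         calls$transcript)]
  attr(results, "det_counts") <- table(results$status)
  class(results) <- c("de_results", "data.frame")
  results
}

#' @export
print.de_results <- function(x, ...) {
  cat("de_results:", nrow(x), "transcripts\n")
  if (!all(is.na(x$status))) print(table(x$status))
  invisible(as.data.frame(x))
}
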