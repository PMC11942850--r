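#' Per-caste expression correlation matrix
#'
#' Pearson correlation between transcripts across the samples of one
#' caste, computed on `log2(TMM + 1)` by default. Transcripts constant
#' across the subset get correlation 0 with everything and are flagged.
#'
#' @param tmm_subset numeric matrix, transcripts x samples (one caste's
#'   columns of the TMM matrix).
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return correlation matrix with attribute `"constant"` (logical vector
#'   marking constant transcripts).
#' @export
correlation_matrix <- function(tmm_subset, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  if (ncol(tmm_subset) < 3) stop("need at least 3 samples per caste")
  x <- if (transform == "log2p1") log2(tmm_subset + 1) else tmm_subset
  const <- apply(x, 1, stats::sd) == 0
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[const, ] <- 0
  cc[, const] <- 0
  diag(cc) <- 1
  attr(cc, "constant") <- const
  cc
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted-network adjacency `a_ij = |cor_ij|^beta`, with the
#' diagonal set to 0 for the downstream topological-overlap computation.
#'
#' @param cor correlation matrix (entries in `[-1, 1]`).
#' @param beta soft-thresholding power (> 0; default 12).
#' @export
soft_adjacency <- function(cor, beta = 12) {
  if (beta <= 0) stop("beta must be positive")
  a <- abs(cor)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` with `k_i = sum_u a_iu`, and `TOM_ii = 1`. Shared-neighbor
#' agreement augments direct adjacency, the standard weighted-network
#' overlap measure.
#'
#' @param adjacency symmetric matrix, zero diagonal, entries in `[0, 1]`.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  L <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

# off-diagonal quantile of a symmetric matrix
offdiag_quantile <- function(m, p) {
  stats::quantile(m[upper.tri(m)], probs = p, names = FALSE)
}

#' Quantile-scale a TOM onto a reference TOM's scale
#'
#' Power-transforms `tom` so that its `scale_quantile` off-diagonal
#' quantile equals that of `ref`: `tom' = tom^(log q_ref / log q_tom)`.
#' Used before taking the consensus so neither caste dominates through
#' overall scale.
#'
#' @param tom matrix to rescale.
#' @param ref reference matrix.
#' @param scale_quantile probability (default 0.95).
#' @export
scale_tom <- function(tom, ref, scale_quantile = 0.95) {
  q_ref <- offdiag_quantile(ref, scale_quantile)
  q_tom <- offdiag_quantile(tom, scale_quantile)
  if (q_ref <= 0 || q_ref >= 1 || q_tom <= 0 || q_tom >= 1)
    stop("degenerate scaling quantile")
  out <- tom^(log(q_ref) / log(q_tom))
  diag(out) <- 1
  out
}

#' Consensus topological overlap
#'
#' Scales the second TOM onto the first's scale (see [scale_tom()]) and
#' takes the element-wise minimum.
#'
#' @param tom_worker,tom_soldier TOM matrices over the same node set and
#'   order.
#' @param scale_quantile probability used for quantile scaling.
#' @export
consensus_tom <- function(tom_worker, tom_soldier, scale_quantile = 0.95) {
  stopifnot(all(dim(tom_worker) == dim(tom_soldier)))
  pmin(tom_worker, scale_tom(tom_soldier, tom_worker, scale_quantile))
}

#' Module detection by static tree cut
#'
#' Average-linkage hierarchical clustering on dissimilarity `1 - TOM`,
#' cut at `cut_height`; clusters smaller than `min_size` are labeled 0
#' (unassigned, "grey").
#'
#' @param consensus consensus TOM matrix.
#' @param cut_height static cut height on the dendrogram (default 0.995).
#' @param min_size minimum module size (default 10).
#' @return integer vector of module labels (0 = unassigned), named by node.
#' @export
detect_modules <- function(consensus, cut_height = 0.995, min_size = 10) {
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  # tied merge heights can come out of order by floating-point jitter
  hc$height <- cummax(hc$height)
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  out <- integer(length(cl))
  for (i in seq_along(keep)) out[cl == as.integer(keep[i])] <- i
  stats::setNames(out, rownames(consensus))
}

#' Per-caste co-expression network
#'
#' Convenience constructor running correlation, soft-threshold adjacency,
#' TOM, consensus and module detection for both castes. Edge weights used
#' for strong-pair extraction are the consensus-scaled per-caste TOMs
#' (`weight = "tom"`, the conventional exported edge weight); raw
#' adjacency is available with `weight = "adjacency"`.
#'
#' @param tmm a `tmm_norm`.
#' @param beta soft-thresholding power.
#' @param transform expression transform for the correlation.
#' @param scale_quantile consensus scaling quantile.
#' @param cut_height,min_size module-detection parameters.
#' @param weight `"tom"` (default) or `"adjacency"`.
#' @return list of class `caste_network`: `nodes`, `weight_worker`,
#'   `weight_soldier` (matrices used for pair extraction), `consensus`,
#'   `modules`, `weight_kind`.
#' @export
build_caste_networks <- function(tmm, beta = 12, transform = "log2p1",
                                 scale_quantile = 0.95, cut_height = 0.995,
                                 min_size = 10, weight = c("tom",
                                                           "adjacency")) {
  weight <- match.arg(weight)
  w <- tmm$caste == "worker"
  cw <- correlation_matrix(tmm$tmm[, w, drop = FALSE], transform)
  cs <- correlation_matrix(tmm$tmm[, !w, drop = FALSE], transform)
  aw <- soft_adjacency(cw, beta)
  as_ <- soft_adjacency(cs, beta)
  tw <- topological_overlap(aw)
  ts <- topological_overlap(as_)
  cons <- consensus_tom(tw, ts, scale_quantile)
  modules <- detect_modules(cons, cut_height, min_size)
  if (weight == "tom") {
    ww <- tw
    ws <- scale_tom(ts, tw, scale_quantile)
  } else {
    ww <- aw; ws <- as_
    diag(ww) <- 1; diag(ws) <- 1
  }
  structure(list(nodes = rownames(tmm$tmm), weight_worker = ww,
                 weight_soldier = ws, consensus = cons, modules = modules,
                 weight_kind = weight, beta = beta),
            class = "caste_network")
}

#' @export
print.caste_network <- function(x, ...) {
  cat("caste_network:", length(x$nodes), "nodes; weight =", x$weight_kind,
      "; beta =", x$beta, ";", max(x$modules), "modules\n")
  invisible(x)
}

#' Extract flagellate-other strong pairs from one caste's network
#'
#' Returns unordered transcript pairs with edge weight at or above the
#' threshold (inclusive) in which one member is a flagellate call and the
#' partner is of another class: termite, unclear, or a flagellate left
#' unclassified at the order level.
#'
#' @param weight_matrix symmetric edge-weight matrix for one caste.
#' @param calls a `source_calls` data frame covering all nodes.
#' @param threshold inclusive weight threshold (default 0.5).
#' @return data frame `flagellate`, `partner`, `partner_class`, `weight`
#'   (one row per unordered pair).
#' @export
strong_pairs <- function(weight_matrix, calls, threshold = 0.5) {
  ids <- rownames(weight_matrix)
  src <- calls$source[match(ids, calls$transcript)]
  ord <- calls$order[match(ids, calls$transcript)]
  if (anyNA(src)) stop("calls must cover every network node")
  is_fl <- src == "flagellate"
  partner_class <- ifelse(src == "termite", "termite",
                   ifelse(src == "unclear", "unclear",
                   ifelse(is.na(ord), "flagellate-unclassified",
                          "flagellate-classified")))
  idx <- which(upper.tri(weight_matrix) & weight_matrix >= threshold,
               arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(flagellate = character(0), partner = character(0),
                      partner_class = character(0), weight = numeric(0)))
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    # orient: flagellate member first; partner must be of another class
    for (pair in list(c(i, j), c(j, i))) {
      a <- pair[1]; b <- pair[2]
      if (is_fl[a] && partner_class[b] %in%
          c("termite", "unclear", "flagellate-unclassified")) {
        # avoid double-counting two unclassified flagellates: keep one
        # orientation only
        if (is_fl[b] && is.na(ord[a]) && a > b) next
        return(data.frame(flagellate = ids[a], partner = ids[b],
                          partner_class = partner_class[b],
                          weight = weight_matrix[a, b],
                          stringsAsFactors = FALSE))
      }
    }
    NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(flagellate = character(0), partner = character(0),
                      partner_class = character(0), weight = numeric(0))
  rownames(out) <- NULL
  out
}

pair_key <- function(pairs) {
  apply(cbind(pairs$flagellate, pairs$partner), 1, function(x)
    paste(sort(x), collapse = "\r"))
}

#' Pairs strong in both castes
#'
#' Intersection of two strong-pair lists on unordered transcript-id pairs.
#'
#' @param worker_pairs,soldier_pairs data frames from [strong_pairs()].
#' @return subset of `worker_pairs` whose unordered pair also appears in
#'   `soldier_pairs`, with both weights attached.
#' @export
shared_pairs <- function(worker_pairs, soldier_pairs) {
  kw <- pair_key(worker_pairs)
  ks <- pair_key(soldier_pairs)
  shared <- worker_pairs[kw %in% ks, , drop = FALSE]
  if (nrow(shared) > 0) {
    names(shared)[names(shared) == "weight"] <- "weight_worker"
    shared$weight_soldier <-
      soldier_pairs$weight[match(kw[kw %in% ks], ks)]
  }
  rownames(shared) <- NULL
  shared
}
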