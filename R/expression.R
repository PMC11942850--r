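#' Read a count matrix and caste map
#'
#' `counts.tsv` has a header; its first column holds transcript ids and the
#' remaining columns one sample each. `castes.tsv` has columns
#' `sample` and `caste` (`worker` or `soldier`).
#'
#' @param counts_path path to the counts TSV.
#' @param castes_path path to the caste map TSV.
#' @return a `count_matrix`: list with integer matrix `counts`
#'   (transcripts x samples) and factor `caste` aligned to columns.
#' @export
read_counts <- function(counts_path, castes_path) {
  df <- utils::read.delim(counts_path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  cm <- utils::read.delim(castes_path, header = TRUE, sep = "\t")
  caste <- stats::setNames(as.character(cm$caste), cm$sample)[colnames(m)]
  if (anyNA(caste)) stop("caste map missing sample(s): ",
                         paste(colnames(m)[is.na(caste)], collapse = ", "))
  count_matrix(m, caste)
}

#' Construct a count matrix object
#'
#' @param counts integer matrix, transcripts in rows, samples in columns.
#' @param caste character/factor of caste labels per sample.
#' @return list of class `count_matrix`.
#' @export
count_matrix <- function(counts, caste) {
  if (any(counts < 0)) stop("negative counts")
  if (length(caste) != ncol(counts)) stop("caste labels must cover samples")
  structure(list(counts = counts,
                 caste = factor(caste, levels = c("worker", "soldier"))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x", ncol(x$counts),
      "samples (", sum(x$caste == "worker"), "worker /",
      sum(x$caste == "soldier"), "soldier )\n")
  invisible(x)
}

#' Counts per million
#'
#' `CPM[g, j] = counts[g, j] / N_j * 1e6` with `N_j` the library size
#' (column sum). Every column of the result sums to one million.
#'
#' @param counts integer matrix or `count_matrix`.
#' @return numeric matrix of the same shape.
#' @export
cpm <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  N <- colSums(m)
  if (any(N == 0)) stop("zero library size in sample(s): ",
                        paste(colnames(m)[N == 0], collapse = ", "))
  sweep(m, 2, N, "/") * 1e6
}

#' Low-expression filter
#'
#' Keeps a transcript iff strictly more than `min_samples` samples show
#' CPM strictly greater than `min_cpm`. Both comparisons are strict, so
#' with the defaults a transcript needs CPM > 1 in at least 11 samples.
#'
#' @param counts a `count_matrix`.
#' @param min_cpm CPM threshold (default 1.0).
#' @param min_samples sample-count threshold (default 10).
#' @return filtered `count_matrix` (same samples, subset of transcripts).
#' @export
filter_low_expression <- function(counts, min_cpm = 1.0, min_samples = 10) {
  keep <- rowSums(cpm(counts) > min_cpm) > min_samples
  count_matrix(counts$counts[keep, , drop = FALSE], counts$caste)
}

# TMM factor for one sample against the reference (edgeR-style trimmed,
# weighted mean of M-values); returns 1 when nothing survives the trim.
tmm_pair_factor <- function(x, xr, logratio_trim, abs_trim) {
  x <- as.numeric(x); xr <- as.numeric(xr)
  N <- sum(x); Nr <- sum(xr)
  keep <- x > 0 & xr > 0
  x <- x[keep]; xr <- xr[keep]
  if (length(x) == 0) stop("sample shares no positive transcript with the ",
                           "reference")
  M <- log2((x / N) / (xr / Nr))
  A <- 0.5 * log2((x / N) * (xr / Nr))
  # delta-method binomial variance of M; weights are inverse variance
  v <- (N - x) / (N * x) + (Nr - xr) / (Nr * xr)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  f <- 2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  if (!is.finite(f) || f <= 0) 1 else f
}

#' Trimmed mean of M-values normalization
#'
#' Computes per-sample TMM scaling factors and the normalized expression
#' matrix. The reference sample is the one whose upper-quartile CPM is
#' closest to the mean upper-quartile. For each sample, log-ratios M and
#' log-abundances A are formed against the reference over transcripts
#' positive in both; the extreme `logratio_trim` fraction by M and
#' `abs_trim` fraction by A are trimmed, and the factor is the
#' precision-weighted mean of the surviving M-values (delta-method
#' binomial weights). Factors are rescaled so their geometric mean is 1.
#' The TMM matrix entry is `counts[g, j] / (N_j * f_j) * 1e6`.
#'
#' @param counts a `count_matrix` (already low-expression filtered).
#' @param logratio_trim two-sided trim fraction on M (default 0.30).
#' @param abs_trim two-sided trim fraction on A (default 0.05).
#' @return list of class `tmm_norm`: `factors` (named numeric),
#'   `effective_libsize`, `reference` (sample id), `tmm` (numeric matrix),
#'   `caste`.
#' @export
tmm_normalize <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  m <- counts$counts
  if (ncol(m) < 2) stop("TMM needs at least 2 samples")
  N <- colSums(m)
  uq <- apply(cpm(m), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(m[, j], m[, ref], logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  eff <- N * f
  tmm <- sweep(m, 2, eff, "/") * 1e6
  structure(list(factors = stats::setNames(f, colnames(m)),
                 effective_libsize = stats::setNames(eff, colnames(m)),
                 reference = colnames(m)[ref],
                 tmm = tmm, caste = counts$caste),
            class = "tmm_norm")
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat("tmm_norm:", nrow(x$tmm), "transcripts x", ncol(x$tmm),
      "samples; reference =", x$reference, "\n")
  cat("  factors:", paste(sprintf("%.3f", x$factors), collapse = " "), "\n")
  invisible(x)
}

#' Write a count or TMM matrix as TSV
#' @param m matrix with row names (transcript ids).
#' @param path output path.
#' @param id_col name of the first (id) column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "transcript") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
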