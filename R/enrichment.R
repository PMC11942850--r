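#' Read a transcript-to-term annotation map
#'
#' Two-column TSV (`transcript`, `term`), one association per line, with a
#' header.
#'
#' @param path annotation TSV path.
#' @return named list: term id -> character vector of transcript ids.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  split(df[[1]], df[[2]])
}

#' True-path propagation of annotations
#'
#' Annotates every transcript to all ancestors of its terms under the
#' given parent DAG, so term counts are ancestor-closed.
#'
#' @param annot named list term -> transcripts.
#' @param dag named list term -> character vector of parent terms (may be
#'   empty or omit terms with no parents).
#' @return annotation list with propagated memberships.
#' @export
propagate_annotations <- function(annot, dag) {
  if (length(dag) == 0) return(annot)
  terms <- union(names(annot), union(names(dag), unlist(dag)))
  # ancestor closure per term, with cycle detection
  anc_cache <- list()
  ancestors <- function(term, seen = character(0)) {
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    if (term %in% seen) stop("cycle detected in term DAG at ", term)
    parents <- dag[[term]]
    if (is.null(parents) || length(parents) == 0) {
      res <- character(0)
    } else {
      res <- parents
      for (p in parents)
        res <- union(res, ancestors(p, c(seen, term)))
    }
    anc_cache[[term]] <<- res
    res
  }
  out <- annot
  for (term in names(annot)) {
    for (a in ancestors(term)) {
      out[[a]] <- union(out[[a]], annot[[term]])
    }
  }
  out
}

#' Hypergeometric over-representation test
#'
#' For each annotated term with at least one background member, tests
#' whether the foreground hits the term more often than expected under
#' sampling without replacement: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`, where `N` is the annotated background
#' size, `K` the term's background hits, `n` the annotated foreground
#' size and `k` the term's foreground hits. p-values are BH-adjusted
#' across the tested terms. Transcripts with no annotation are dropped
#' from both sets (their count is reported in the `dropped` attribute).
#'
#' @param foreground character vector of transcript ids (subset of
#'   `background`).
#' @param background character vector of transcript ids (the universe).
#' @param annot named list term -> transcripts.
#' @return data frame of class `enrichment_result`: `term`, `k`, `n`,
#'   `K`, `N`, `p`, `q`, ordered by `p`.
#' @export
hypergeom_enrich <- function(foreground, background, annot) {
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  annotated <- unique(unlist(annot))
  bg <- intersect(background, annotated)
  fg <- intersect(foreground, annotated)
  dropped <- c(foreground = length(foreground) - length(fg),
               background = length(background) - length(bg))
  N <- length(bg); n <- length(fg)
  rows <- lapply(names(annot), function(term) {
    members <- intersect(annot[[term]], bg)
    K <- length(members)
    if (K < 1) return(NULL)
    k <- length(intersect(members, fg))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0))
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result:", nrow(x), "terms tested;",
      sum(x$q < 0.05), "significant at q < 0.05\n")
  invisible(as.data.frame(x))
}

#' Significant-term report
#'
#' Filters enrichment rows to `q < alpha`, sorted by q. When
#' `min_transcripts` is given (default 5), a second reporting filter
#' keeps terms with strictly more than that many associated foreground
#' transcripts, the convention used for displayed term tables.
#'
#' @param rows an `enrichment_result`.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param min_transcripts strict lower bound on foreground hits for the
#'   reported table (`NULL` disables the filter).
#' @return data frame of significant rows.
#' @export
enrichment_report <- function(rows, alpha = 0.05, min_transcripts = 5) {
  sig <- rows[!is.na(rows$q) & rows$q < alpha, , drop = FALSE]
  sig <- sig[order(sig$q, sig$term), , drop = FALSE]
  if (!is.null(min_transcripts))
    sig <- sig[sig$k > min_transcripts, , drop = FALSE]
  rownames(sig) <- NULL
  sig
}
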