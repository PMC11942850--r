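#' Published reference tables
#'
#' Accessors for the published summary tables from a worker/soldier
#' metatranscriptome study of a kalotermitid lower termite
#' (*Neotermes binovatus*) and its hindgut flagellates, shipped as
#' plain-text files. They serve as worked inputs for the tabulation and
#' reporting operations:
#'
#' * `published_biomarker_table()` - the 12 lasso caste-biomarker
#'   transcripts with putative source, coefficient, mean worker/soldier
#'   TMM expression and DET flag.
#' * `published_flagellate_gene_counts()` - flagellate transcript counts
#'   by gene class and flagellate order (long format, inner cells only).
#' * `published_genus_calls()` - the ten genus-level 18S rRNA calls with
#'   best-hit identity, mean TMM per caste and adjusted p.
#'
#' @return a data frame (see above).
#' @name published_tables
NULL

#' @rdname published_tables
#' @export
published_biomarker_table <- function() {
  utils::read.delim(system.file("extdata", "caste_biomarkers.tsv",
                                package = "symbiopart"),
                    sep = "\t", check.names = FALSE)
}

#' @rdname published_tables
#' @export
published_flagellate_gene_counts <- function() {
  utils::read.delim(system.file("extdata",
                                "flagellate_gene_order_counts.tsv",
                                package = "symbiopart"),
                    sep = "\t", check.names = FALSE)
}

#' @rdname published_tables
#' @export
published_genus_calls <- function() {
  utils::read.delim(system.file("extdata", "flagellate_genus_calls.tsv",
                                package = "symbiopart"),
                    sep = "\t", check.names = FALSE)
}

#' Expand a gene-by-order count table into per-transcript source calls
#'
#' Reconstructs one flagellate source call (and its gene label) per
#' counted transcript from a long-format gene/order/count table, so the
#' tabulator can be exercised against published totals.
#'
#' @param counts_long data frame with columns `gene`, `order`, `count`
#'   (order `"unclassified"` for order-unresolved transcripts).
#' @return list: `calls` (a `source_calls` data frame with order names in
#'   the `order` column) and `gene_labels` (named character vector).
#' @export
expand_gene_order_counts <- function(counts_long) {
  counts_long <- counts_long[counts_long$count > 0, , drop = FALSE]
  n <- sum(counts_long$count)
  ids <- sprintf("pub_%04d", seq_len(n))
  gene <- rep(counts_long$gene, counts_long$count)
  ord <- rep(counts_long$order, counts_long$count)
  calls <- data.frame(transcript = ids, source = "flagellate",
                      order = ifelse(ord == "unclassified", NA, ord),
                      genus = NA_character_,
                      best_sseqid = NA_character_,
                      best_pident = NA_real_, rule = "published",
                      stringsAsFactors = FALSE)
  class(calls) <- c("source_calls", "data.frame")
  list(calls = calls, gene_labels = stats::setNames(gene, ids))
}
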