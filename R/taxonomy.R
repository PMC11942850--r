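#' Load a taxonomy table
#'
#' Reads a taxonomy into a validated lookup structure used by the source
#' classifier. Two dialects are supported:
#'
#' * `"simple-tsv"`: a four-column tab-separated file with a header line
#'   `taxid  parent  rank  name`.
#' * `"ncbi-dump"`: a pair of pipe-delimited NCBI-style dump files. `path`
#'   must name the `nodes.dmp` file; the matching `names.dmp` is looked up
#'   in the same directory (or passed via `names_path`). Only the
#'   "scientific name" class is read from `names.dmp`.
#'
#' The table must contain exactly one root (a node whose parent is itself),
#' every parent must be present, and no cycles are allowed.
#'
#' @param path path to the taxonomy file (`nodes.dmp` for `"ncbi-dump"`).
#' @param dialect `"simple-tsv"` (default) or `"ncbi-dump"`.
#' @param names_path optional explicit path to `names.dmp` for the
#'   `"ncbi-dump"` dialect.
#' @return an object of class `taxonomy_table`: a list with integer vectors
#'   `taxid`, `parent` and character vectors `rank`, `name`, indexed by
#'   taxid through an internal hash.
#' @export
load_taxonomy <- function(path, dialect = c("simple-tsv", "ncbi-dump"),
                          names_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  if (dialect == "simple-tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = c("integer", "integer",
                                           "character", "character"),
                            quote = "", comment.char = "")
    names(df) <- c("taxid", "parent", "rank", "name")
  } else {
    nodes <- readLines(path)
    fields <- strsplit(nodes, "\t\\|\t?")
    taxid <- vapply(fields, function(f) as.integer(f[1]), integer(1))
    parent <- vapply(fields, function(f) as.integer(f[2]), integer(1))
    rank <- vapply(fields, function(f) f[3], character(1))
    if (is.null(names_path))
      names_path <- file.path(dirname(path), "names.dmp")
    if (!file.exists(names_path))
      stop("names.dmp not found for ncbi-dump dialect: ", names_path)
    nm_lines <- readLines(names_path)
    nm_fields <- strsplit(nm_lines, "\t\\|\t?")
    nm_class <- vapply(nm_fields, function(f) sub("\t\\|$", "", f[4]),
                       character(1))
    sci <- nm_fields[trimws(nm_class) == "scientific name"]
    nm_taxid <- vapply(sci, function(f) as.integer(f[1]), integer(1))
    nm_name <- vapply(sci, function(f) f[2], character(1))
    name <- nm_name[match(taxid, nm_taxid)]
    name[is.na(name)] <- as.character(taxid[is.na(name)])
    df <- data.frame(taxid = taxid, parent = parent, rank = rank,
                     name = name, stringsAsFactors = FALSE)
  }
  build_taxonomy(df)
}

#' Build a taxonomy table from a data frame
#'
#' @param df data frame with columns `taxid`, `parent`, `rank`, `name`.
#' @return a validated `taxonomy_table`.
#' @export
build_taxonomy <- function(df) {
  stopifnot(all(c("taxid", "parent", "rank", "name") %in% names(df)))
  taxid <- as.integer(df$taxid)
  parent <- as.integer(df$parent)
  if (anyDuplicated(taxid)) stop("duplicate taxid in taxonomy")
  if (anyNA(taxid) || anyNA(parent)) stop("non-integer taxid or parent")
  missing_parent <- setdiff(parent, taxid)
  if (length(missing_parent) > 0)
    stop("missing parent taxid(s): ", paste(missing_parent, collapse = ", "))
  roots <- taxid[taxid == parent]
  if (length(roots) != 1)
    stop("taxonomy must have exactly one root, found ", length(roots))
  tax <- structure(list(taxid = taxid, parent = parent,
                        rank = as.character(df$rank),
                        name = as.character(df$name),
                        root = roots,
                        index = stats::setNames(seq_along(taxid),
                                                as.character(taxid))),
                   class = "taxonomy_table")
  # cycle check: every node must reach the root
  for (t in taxid) lineage(t, tax)
  tax
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat("taxonomy_table:", length(x$taxid), "nodes, root taxid", x$root, "\n")
  rk <- table(x$rank)
  cat("  ranks:", paste(names(rk), rk, sep = ":", collapse = " "), "\n")
  invisible(x)
}

tax_idx <- function(taxid, tax) {
  i <- tax$index[[as.character(taxid)]]
  if (is.null(i)) stop("unknown taxid: ", taxid)
  i
}

#' Root-to-node lineage
#'
#' @param taxid query taxid (must be present in `tax`).
#' @param tax a `taxonomy_table`.
#' @return integer vector of taxids ordered root first, query last.
#' @export
lineage <- function(taxid, tax) {
  i <- tax_idx(taxid, tax)
  path <- integer(0)
  n <- length(tax$taxid)
  for (step in seq_len(n + 1)) {
    path <- c(tax$taxid[i], path)
    p <- tax$parent[i]
    if (p == tax$taxid[i]) return(path)
    i <- tax_idx(p, tax)
  }
  stop("cycle detected in taxonomy at taxid ", taxid)
}

#' Clade membership
#'
#' `TRUE` iff `clade_taxid` lies on the lineage of `taxid` (a node is in
#' its own clade).
#'
#' @inheritParams lineage
#' @param clade_taxid taxid of the clade ancestor.
#' @export
in_clade <- function(taxid, clade_taxid, tax) {
  clade_taxid %in% lineage(taxid, tax)
}

#' Ancestor of a node at a given rank
#'
#' Walks the lineage of `taxid` and returns the unique node whose rank label
#' equals `rank`, or `NA` if no lineage node has that rank.
#'
#' @inheritParams lineage
#' @param rank free-text rank label, e.g. `"order"` or `"genus"`.
#' @return taxid (integer) or `NA_integer_`.
#' @export
ancestor_at_rank <- function(taxid, rank, tax) {
  lin <- lineage(taxid, tax)
  ranks <- tax$rank[vapply(lin, function(t) tax_idx(t, tax), integer(1))]
  hit <- lin[ranks == rank]
  if (length(hit) == 0) return(NA_integer_)
  hit[length(hit)]  # closest to the query if rank repeats
}

#' Name of a taxonomy node
#' @inheritParams lineage
#' @export
taxon_name <- function(taxid, tax) tax$name[tax_idx(taxid, tax)]

#' Write a taxonomy table in the simple TSV dialect
#' @param tax a `taxonomy_table`.
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  df <- data.frame(taxid = tax$taxid, parent = tax$parent,
                   rank = tax$rank, name = tax$name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
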