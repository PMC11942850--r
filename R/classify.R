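#' Parse a 13-column similarity-search hit table
#'
#' Reads a tab-separated hit table in the standard 12-column tabular format
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore) extended with a 13th subject-taxid column, drops hits
#' with E-value above the cutoff, and returns per-query hit lists.
#'
#' @param path hit table path (no header).
#' @param evalue_cutoff hits with `evalue > cutoff` are dropped; the
#'   boundary is retained (default `1e-5`).
#' @return named list: query id -> data frame of `hit_record` rows.
#' @export
parse_hits <- function(path, evalue_cutoff = 1e-5) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  bad <- which(ncols != 13)
  if (length(bad) > 0)
    stop("malformed hit row at line ", bad[1], ": expected 13 columns, got ",
         ncols[bad[1]])
  m <- matrix(unlist(parts), ncol = 13, byrow = TRUE)
  num_cols <- c(3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13)
  vals <- suppressWarnings(apply(m[, num_cols, drop = FALSE], 2, as.numeric))
  vals <- matrix(vals, ncol = length(num_cols))
  if (anyNA(vals)) {
    bad_row <- which(apply(vals, 1, anyNA))[1]
    stop("malformed hit row at line ", bad_row, ": non-numeric field")
  }
  df <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                   pident = vals[, 1], length = vals[, 2],
                   mismatch = vals[, 3], gapopen = vals[, 4],
                   qstart = vals[, 5], qend = vals[, 6],
                   sstart = vals[, 7], send = vals[, 8],
                   evalue = vals[, 9], bitscore = vals[, 10],
                   staxid = as.integer(vals[, 11]),
                   stringsAsFactors = FALSE)
  if (any(df$qstart > df$qend))
    stop("malformed hit row: qstart > qend at line ",
         which(df$qstart > df$qend)[1])
  df <- df[df$evalue <= evalue_cutoff, , drop = FALSE]
  split(df, factor(df$qseqid, levels = unique(df$qseqid)))
}

#' Best hit under the composite ordering
#'
#' Maximal bitscore; ties broken by lower E-value, then higher percent
#' identity, then lexicographically smallest subject id. Deterministic for
#' any input order.
#'
#' @param hits data frame of hits for one query.
#' @return single-row data frame (the winning hit).
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) stop("best_hit: empty hit list")
  o <- order(-hits$bitscore, hits$evalue, -hits$pident, hits$sseqid,
             method = "radix")
  hits[o[1], , drop = FALSE]
}

# union of intervals -> matrix with columns start, end (disjoint, sorted)
interval_union <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(starts)) {
    if (length(out_s) > 0 && starts[i] <= out_e[length(out_e)] + 1) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], ends[i])
    } else {
      out_s <- c(out_s, starts[i]); out_e <- c(out_e, ends[i])
    }
  }
  cbind(start = out_s, end = out_e)
}

# bases of [s, e] (1-based inclusive) not covered by the union `u`
bases_outside <- function(s, e, u) {
  total <- e - s + 1
  covered <- 0
  for (i in seq_len(nrow(u))) {
    lo <- max(s, u[i, 1]); hi <- min(e, u[i, 2])
    if (lo <= hi) covered <- covered + (hi - lo + 1)
  }
  total - covered
}

#' Conflict-region check for a classified transcript
#'
#' A source call requires that hits from organisms outside the focal clade
#' contribute no substantial alignment outside the best-hit region. The
#' best-hit region `B` is the union of the query intervals of every hit to
#' the best subject sequence (multi-HSP subjects count as one match).
#' Returns `FALSE` iff some hit with a taxid outside `focal_clade` has more
#' than `tolerance_bp` aligned query bases outside `B`.
#'
#' @param hits data frame of hits for one query (best included).
#' @param best the best hit row (as returned by [best_hit()]).
#' @param focal_clade clade taxid defining "same organism group".
#' @param tax a `taxonomy_table`.
#' @param tolerance_bp allowed overhang in bases (default 30; 0 = strict).
#' @export
conflict_free <- function(hits, best, focal_clade, tax, tolerance_bp = 30) {
  same_subj <- hits$sseqid == best$sseqid
  B <- interval_union(hits$qstart[same_subj], hits$qend[same_subj])
  other <- which(!vapply(hits$staxid, in_clade, logical(1),
                         clade_taxid = focal_clade, tax = tax))
  for (i in other) {
    if (bases_outside(hits$qstart[i], hits$qend[i], B) > tolerance_bp)
      return(FALSE)
  }
  TRUE
}

#' Classification parameters
#'
#' @param host_clade host clade taxid (default 85823, Blattodea).
#' @param symbiont_clade symbiont clade taxid (default 2611341, Metamonada).
#' @param tolerance_bp conflict-region tolerance in bases.
#' @param order_pident strict lower bound on percent identity for the
#'   order-level consensus (default 80).
#' @param genus_pident strict lower bound for the genus-level consensus
#'   (default 90).
#' @param min_consensus_hits number of symbiont-clade hits the consensus
#'   requires; the default 5 demands exactly five qualifying hits, the
#'   strict reading of the top-five rule. Lowering it allows consensus
#'   calls from fewer hits.
#' @return list of class `classify_params`.
#' @export
classify_params <- function(host_clade = 85823L, symbiont_clade = 2611341L,
                            tolerance_bp = 30, order_pident = 80,
                            genus_pident = 90, min_consensus_hits = 5L) {
  structure(list(host_clade = as.integer(host_clade),
                 symbiont_clade = as.integer(symbiont_clade),
                 tolerance_bp = tolerance_bp,
                 order_pident = order_pident,
                 genus_pident = genus_pident,
                 min_consensus_hits = as.integer(min_consensus_hits)),
            class = "classify_params")
}

#' Classify one transcript from its hits
#'
#' Implements the best-hit partitioning rule: a transcript is called host
#' (termite) iff its best hit falls inside the host clade and the
#' conflict-region check passes; symbiont (flagellate) iff the best hit
#' falls inside the symbiont clade and the check passes; otherwise
#' unclear (including transcripts with no hits). For flagellate calls the
#' symbiont-clade hits are ranked by the best-hit ordering and truncated to
#' the top five: if exactly five qualify, all with percent identity
#' strictly above 80 and all resolving to one order, the order is assigned;
#' if all five are strictly above 90 and resolve to a single genus, the
#' genus is assigned as well. A genus call implies its lineage order; if a
#' genus-derived order would contradict the order consensus the genus is
#' dropped.
#'
#' @param hits data frame of hits for the transcript (already E-value
#'   filtered), or `NULL`/empty for a no-hit transcript.
#' @param tax a `taxonomy_table`.
#' @param params a [classify_params()] list.
#' @param id transcript id (used when `hits` is empty).
#' @return one-row data frame: `transcript`, `source` (one of `"termite"`,
#'   `"flagellate"`, `"unclear"`), `order` / `genus` taxids (`NA` unless
#'   assigned), `best_sseqid`, `best_pident`, `rule` (short trace).
#' @export
classify_transcript <- function(hits, tax, params = classify_params(),
                                id = NULL) {
  call_row <- function(id, source, order = NA_integer_, genus = NA_integer_,
                       best_sseqid = NA_character_, best_pident = NA_real_,
                       rule = "") {
    data.frame(transcript = id, source = source, order = order,
               genus = genus, best_sseqid = best_sseqid,
               best_pident = best_pident, rule = rule,
               stringsAsFactors = FALSE)
  }
  if (is.null(hits) || nrow(hits) == 0) {
    if (is.null(id)) stop("classify_transcript: empty hits and no id")
    return(call_row(id, "unclear", rule = "no-hit"))
  }
  id <- hits$qseqid[1]
  best <- best_hit(hits)
  known <- vapply(hits$staxid, function(t)
    !is.null(tax$index[[as.character(t)]]), logical(1))
  if (!all(known)) stop("hit staxid absent from taxonomy: ",
                        hits$staxid[!known][1])
  in_host <- in_clade(best$staxid, params$host_clade, tax)
  in_sym <- in_clade(best$staxid, params$symbiont_clade, tax)
  if (in_host) {
    if (conflict_free(hits, best, params$host_clade, tax,
                      params$tolerance_bp))
      return(call_row(id, "termite", best_sseqid = best$sseqid,
                      best_pident = best$pident, rule = "best-hit-host"))
    return(call_row(id, "unclear", best_sseqid = best$sseqid,
                    best_pident = best$pident, rule = "host-conflict"))
  }
  if (!in_sym)
    return(call_row(id, "unclear", best_sseqid = best$sseqid,
                    best_pident = best$pident, rule = "best-hit-other"))
  if (!conflict_free(hits, best, params$symbiont_clade, tax,
                     params$tolerance_bp))
    return(call_row(id, "unclear", best_sseqid = best$sseqid,
                    best_pident = best$pident, rule = "symbiont-conflict"))
  # flagellate: order/genus consensus over the top-5 symbiont-clade hits
  sym <- hits[vapply(hits$staxid, in_clade, logical(1),
                     clade_taxid = params$symbiont_clade, tax = tax), ,
              drop = FALSE]
  o <- order(-sym$bitscore, sym$evalue, -sym$pident, sym$sseqid,
             method = "radix")
  top <- sym[o[seq_len(min(5L, nrow(sym)))], , drop = FALSE]
  order_id <- NA_integer_; genus_id <- NA_integer_
  rule <- "best-hit-symbiont"
  if (nrow(top) >= params$min_consensus_hits && nrow(top) <= 5L &&
      all(top$pident > params$order_pident)) {
    ords <- vapply(top$staxid, ancestor_at_rank, integer(1),
                   rank = "order", tax = tax)
    if (!anyNA(ords) && length(unique(ords)) == 1L) {
      order_id <- ords[1]
      rule <- paste0(rule, "+order-consensus")
    }
    if (all(top$pident > params$genus_pident)) {
      gens <- vapply(top$staxid, ancestor_at_rank, integer(1),
                     rank = "genus", tax = tax)
      if (!anyNA(gens) && length(unique(gens)) == 1L) {
        g_order <- ancestor_at_rank(gens[1], "order", tax)
        if (is.na(order_id)) {
          # genus consensus implies the lineage order
          genus_id <- gens[1]
          order_id <- g_order
          rule <- paste0(rule, "+genus-consensus")
        } else if (!is.na(g_order) && g_order == order_id) {
          genus_id <- gens[1]
          rule <- paste0(rule, "+genus-consensus")
        }
      }
    }
  }
  call_row(id, "flagellate", order = order_id, genus = genus_id,
           best_sseqid = best$sseqid, best_pident = best$pident, rule = rule)
}

#' Classify every transcript in a hit map
#'
#' @param hit_map named list from [parse_hits()].
#' @param tax a `taxonomy_table`.
#' @param params a [classify_params()] list.
#' @param all_ids optional character vector of transcript ids; ids absent
#'   from `hit_map` are called unclear (no hits).
#' @return data frame of class `source_calls`, one row per transcript.
#' @export
classify_transcripts <- function(hit_map, tax, params = classify_params(),
                                 all_ids = NULL) {
  ids <- names(hit_map)
  if (!is.null(all_ids)) ids <- union(all_ids, ids)
  rows <- lapply(ids, function(i)
    classify_transcript(hit_map[[i]], tax, params, id = i))
  calls <- do.call(rbind, rows)
  if (is.null(calls))
    calls <- data.frame(transcript = character(0), source = character(0),
                        order = integer(0), genus = integer(0),
                        best_sseqid = character(0), best_pident = numeric(0),
                        rule = character(0))
  rownames(calls) <- NULL
  class(calls) <- c("source_calls", "data.frame")
  calls
}

#' @export
print.source_calls <- function(x, ...) {
  cat("source_calls:", nrow(x), "transcripts\n")
  print(table(x$source))
  invisible(as.data.frame(x))
}

#' Tabulate flagellate calls by gene class and order
#'
#' Builds an order-by-gene count table of flagellate source calls with row
#' and column totals, mirroring the standard flagellate identification
#' summary. Transcripts not classified to any order are counted under
#' `"unclassified"`; transcripts missing from `gene_labels` are counted
#' under `"others"` with a warning.
#'
#' @param calls a `source_calls` data frame.
#' @param gene_labels named character vector: transcript id -> gene class
#'   label (e.g. "18S rRNA", "actin", "others").
#' @param tax optional `taxonomy_table` used to render order taxids as
#'   names; when `NULL`, `calls$order` may already contain names.
#' @return matrix of counts, gene classes in rows (plus `"total"`), orders
#'   in columns (plus `"unclassified"` and `"total"`).
#' @export
tabulate_sources <- function(calls, gene_labels, tax = NULL) {
  fl <- calls[calls$source == "flagellate", , drop = FALSE]
  lab <- gene_labels[fl$transcript]
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " flagellate transcript(s) missing from ",
            "gene_labels; counted as 'others'")
    lab[is.na(lab)] <- "others"
  }
  ord <- fl$order
  if (!is.null(tax) && is.numeric(ord)) {
    ord <- ifelse(is.na(ord), "unclassified",
                  vapply(ord, function(t)
                    if (is.na(t)) "unclassified" else taxon_name(t, tax),
                    character(1)))
  } else {
    ord <- ifelse(is.na(ord) | ord == "", "unclassified", as.character(ord))
  }
  gene_levels <- unique(c(unique(unname(gene_labels)), "others"))
  order_levels <- unique(c(setdiff(unique(ord), "unclassified"),
                           "unclassified"))
  tab <- table(factor(lab, levels = gene_levels),
               factor(ord, levels = order_levels))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m <- rbind(m, total = colSums(m))
  m <- cbind(m, total = rowSums(m))
  storage.mode(m) <- "integer"
  m
}
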