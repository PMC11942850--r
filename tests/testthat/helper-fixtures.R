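# Shared fixtures built in code.

# A minimal hand-written taxonomy: root -> two clades with order/genus tiers.
tiny_taxonomy <- function() {
  build_taxonomy(data.frame(
    taxid  = c(1L, 10L, 11L, 12L, 13L, 20L, 21L, 22L, 30L),
    parent = c(1L,  1L, 10L, 11L, 12L,  1L, 20L, 21L,  1L),
    rank   = c("no rank", "phylum", "order", "genus", "species",
               "phylum", "order", "genus", "kingdom"),
    name   = c("root", "CladeA", "OrderA", "GenusA", "SpeciesA",
               "CladeB", "OrderB", "GenusB", "Outgroup")))
}

# One hit row with sensible defaults.
mk_hit <- function(qseqid = "q1", sseqid = "s1", pident = 95, length = 500,
                   qstart = 1, qend = 500, evalue = 1e-50, bitscore = 900,
                   staxid = 13L) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = 0L, gapopen = 0L,
             qstart = qstart, qend = qend, sstart = 1L, send = length,
             evalue = evalue, bitscore = bitscore, staxid = staxid,
             stringsAsFactors = FALSE)
}

write_hits_file <- function(hits) {
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(hits, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tf
}

# Random count matrix helper.
random_counts <- function(n_transcripts, n_samples, seed = 1, mu_log = 5,
                          size = 5) {
  set.seed(seed)
  mu <- exp(rnorm(n_transcripts, mu_log, 1.2))
  m <- matrix(rnbinom(n_transcripts * n_samples, mu = rep(mu, n_samples),
                      size = size),
              n_transcripts, n_samples,
              dimnames = list(sprintf("t%04d", seq_len(n_transcripts)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_matrix(m, rep(c("worker", "soldier"), length.out = n_samples))
}

# source_calls straight from a synthetic truth (bypasses hit simulation).
calls_from_truth <- function(truth) {
  tr <- truth$transcripts
  calls <- data.frame(transcript = tr$id, source = tr$true_source,
                      order = tr$order, genus = tr$genus,
                      best_sseqid = NA_character_, best_pident = NA_real_,
                      rule = "truth", stringsAsFactors = FALSE)
  class(calls) <- c("source_calls", "data.frame")
  calls
}

# exact hypergeometric upper tail by enumeration over all subsets
# (combinat-free; exact for small N)
enum_hyper_p <- function(N, K, n, k) {
  # P(X >= k) by summing the pmf computed from binomial coefficients
  kk <- max(0, k):min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# brute-force BH step-up
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- min(val, 1)
    prev <- val
  }
  q
}

# brute-force TOM by triple loop
brute_tom <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    ki <- sum(a[i, ]); kj <- sum(a[j, ])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}
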