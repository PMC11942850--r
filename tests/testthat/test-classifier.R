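test_that("parse_hits applies the E-value cutoff and validates rows", {
  h <- rbind(mk_hit(evalue = 1e-3), mk_hit(qseqid = "q2", evalue = 1e-5),
             mk_hit(qseqid = "q3", evalue = 1e-50))
  tf <- write_hits_file(h)
  m <- parse_hits(tf, evalue_cutoff = 1e-5)
  expect_false("q1" %in% names(m))          # above cutoff: dropped
  expect_true("q2" %in% names(m))           # boundary retained
  expect_true("q3" %in% names(m))

  # empty file
  tf0 <- tempfile(); file.create(tf0)
  expect_length(parse_hits(tf0), 0)

  # wrong column count names the line
  tf12 <- tempfile()
  writeLines("q1\ts1\t95\t500\t0\t0\t1\t500\t1\t500\t1e-50\t900", tf12)
  expect_error(parse_hits(tf12), "line 1")

  # non-numeric field
  tfx <- tempfile()
  writeLines("q1\ts1\tninety\t500\t0\t0\t1\t500\t1\t500\t1e-50\t900\t13",
             tfx)
  expect_error(parse_hits(tfx), "non-numeric")
})

test_that("best_hit follows the composite key; brute-force agreement", {
  h <- rbind(mk_hit(sseqid = "a", bitscore = 200),
             mk_hit(sseqid = "b", bitscore = 180))
  expect_identical(best_hit(h)$sseqid, "a")
  expect_error(best_hit(h[0, ]), "empty")

  set.seed(21)
  for (rep in 1:100) {
    n <- sample(1:8, 1)
    h <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_hit(sseqid = sample(letters[1:4], 1),
             bitscore = sample(c(100, 200, 300), 1),
             evalue = sample(c(1e-10, 1e-20), 1),
             pident = sample(c(80, 90, 95), 1))))
    b <- best_hit(h)
    # brute force over the composite key
    key <- function(r) c(-r$bitscore, r$evalue, -r$pident)
    best_idx <- 1
    for (i in seq_len(nrow(h))) {
      ki <- key(h[i, ]); kb <- key(h[best_idx, ])
      cmp <- sign(c(ki - kb, ifelse(h$sseqid[i] < h$sseqid[best_idx], -1,
                                    ifelse(h$sseqid[i] > h$sseqid[best_idx],
                                           1, 0))))
      nz <- which(cmp != 0)
      if (length(nz) > 0 && cmp[nz[1]] < 0) best_idx <- i
    }
    expect_identical(b, h[best_idx, , drop = FALSE],
                     ignore_attr = TRUE)
  }
})

test_that("conflict_free interval arithmetic", {
  tax <- tiny_taxonomy()
  # only focal-clade hits: vacuously conflict free
  h <- rbind(mk_hit(sseqid = "best", qstart = 1, qend = 500, staxid = 13L),
             mk_hit(sseqid = "x2", qstart = 100, qend = 300, staxid = 13L))
  expect_true(conflict_free(h, best_hit(h), 10L, tax, 30))

  # fungal hit q[450,700] vs best region [1,500]: 200 bases outside > 30
  h2 <- rbind(mk_hit(sseqid = "best", qstart = 1, qend = 500, staxid = 13L),
              mk_hit(sseqid = "fun", qstart = 450, qend = 700,
                     bitscore = 100, staxid = 30L))
  expect_false(conflict_free(h2, best_hit(h2), 10L, tax, 30))
  # but a 250-bp tolerance absorbs it
  expect_true(conflict_free(h2, best_hit(h2), 10L, tax, 250))

  # fungal hit fully inside the best region
  h3 <- rbind(mk_hit(sseqid = "best", qstart = 1, qend = 500, staxid = 13L),
              mk_hit(sseqid = "fun", qstart = 100, qend = 400,
                     bitscore = 100, staxid = 30L))
  expect_true(conflict_free(h3, best_hit(h3), 10L, tax, 30))

  # multi-HSP best subject: union of its intervals is the best region
  h4 <- rbind(mk_hit(sseqid = "best", qstart = 1, qend = 300, staxid = 13L),
              mk_hit(sseqid = "best", qstart = 600, qend = 900,
                     bitscore = 500, staxid = 13L),
              mk_hit(sseqid = "fun", qstart = 610, qend = 890,
                     bitscore = 100, staxid = 30L))
  expect_true(conflict_free(h4, best_hit(h4), 10L, tax, 0))
})

test_that("classify_transcript implements the partition + consensus rule", {
  cfg <- sim_config()
  tax <- generate_taxonomy(cfg)
  params <- classify_params()
  dev_sp <- 201L * 100L + 1L     # a Devescovina species

  # best hit in the host clade, no conflicting hits -> termite
  h <- mk_hit(staxid = 10101L)   # Neotermes sp1
  expect_identical(classify_transcript(h, tax, params)$source, "termite")

  # five single-genus hits above 90 -> flagellate + order + genus
  h5 <- do.call(rbind, lapply(1:5, function(i)
    mk_hit(sseqid = paste0("s", i), pident = 96 - i,
           bitscore = 900 - 10 * i, staxid = dev_sp)))
  call <- classify_transcript(h5, tax, params)
  expect_identical(call$source, "flagellate")
  expect_identical(taxon_name(call$order, tax), "Cristamonadida")
  expect_identical(taxon_name(call$genus, tax), "Devescovina")

  # mixed orders with one hit at 81: neither order nor genus
  h_mixed <- do.call(rbind, lapply(1:5, function(i)
    mk_hit(sseqid = paste0("s", i), pident = c(95, 94, 93, 92, 81)[i],
           bitscore = 900 - 10 * i,
           staxid = c(20101L, 20101L, 20101L, 20101L, 21101L)[i])))
  call2 <- classify_transcript(h_mixed, tax, params)
  expect_identical(call2$source, "flagellate")
  expect_true(is.na(call2$order) && is.na(call2$genus))

  # exactly-five rule: four qualifying hits leave the order unset
  call3 <- classify_transcript(h5[1:4, ], tax, params)
  expect_true(is.na(call3$order))
  relaxed <- classify_params(min_consensus_hits = 3)
  expect_identical(taxon_name(classify_transcript(h5[1:4, ], tax,
                                                  relaxed)$order, tax),
                   "Cristamonadida")

  # no hits -> unclear, never an error
  expect_identical(classify_transcript(NULL, tax, params, id = "q")$source,
                   "unclear")
})

test_that("hit-row order never changes a call (permutation invariance)", {
  cfg <- sim_config(seed = 31, n_termite = 20, n_flagellate = 20,
                    n_unclear = 10, n_coupled_pairs = 0, decoy_rate = 0.2)
  tax <- generate_taxonomy(cfg)
  truth <- simulate_truth(cfg)
  hits <- simulate_hits(truth, tax, cfg)
  tf <- write_hits_file(hits)
  calls1 <- classify_transcripts(parse_hits(tf), tax,
                                 all_ids = truth$transcripts$id)
  set.seed(1)
  hits2 <- hits[sample.int(nrow(hits)), ]
  tf2 <- write_hits_file(hits2)
  calls2 <- classify_transcripts(parse_hits(tf2), tax,
                                 all_ids = truth$transcripts$id)
  o1 <- order(calls1$transcript); o2 <- order(calls2$transcript)
  expect_identical(calls1[o1, c("transcript", "source", "order", "genus")],
                   calls2[o2, c("transcript", "source", "order", "genus")],
                   ignore_attr = TRUE)
})

test_that("adding a non-focal hit only ever moves a call toward unclear", {
  cfg <- sim_config()
  tax <- generate_taxonomy(cfg)
  params <- classify_params()
  h5 <- do.call(rbind, lapply(1:5, function(i)
    mk_hit(sseqid = paste0("s", i), pident = 96 - i,
           bitscore = 900 - 10 * i, staxid = 20101L)))
  base_call <- classify_transcript(h5, tax, params)$source
  expect_identical(base_call, "flagellate")
  # inside the best region: no change
  inside <- mk_hit(sseqid = "fun", qstart = 10, qend = 400, bitscore = 50,
                   staxid = 30101L)
  expect_identical(classify_transcript(rbind(h5, inside), tax,
                                       params)$source, "flagellate")
  # far outside: unclear
  outside <- mk_hit(sseqid = "fun", qstart = 600, qend = 1000,
                    bitscore = 50, staxid = 30101L)
  expect_identical(classify_transcript(rbind(h5, outside), tax,
                                       params)$source, "unclear")
})

test_that("tabulate_sources counts gene classes by order with totals", {
  calls <- data.frame(
    transcript = c("a", "b", "c", "d"),
    source = c("flagellate", "flagellate", "flagellate", "termite"),
    order = c("OrdA", "OrdA", NA, NA), genus = NA,
    best_sseqid = NA, best_pident = NA, rule = "t")
  class(calls) <- c("source_calls", "data.frame")
  labels <- c(a = "actin", b = "18S rRNA", c = "actin")
  tab <- tabulate_sources(calls, labels)
  expect_equal(tab["actin", "OrdA"], 1)
  expect_equal(tab["actin", "unclassified"], 1)
  expect_equal(tab["total", "total"], 3)   # termite rows not counted
  # missing gene label -> others with warning
  expect_warning(tab2 <- tabulate_sources(calls, labels[1:2]), "others")
  expect_equal(tab2["others", "unclassified"], 1)
  # empty calls
  tab0 <- tabulate_sources(calls[0, ], labels)
  expect_equal(tab0["total", "total"], 0)
})
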