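test_that("synthetic taxonomy has the expected clade structure", {
  tax <- generate_taxonomy(sim_config())
  dev <- 201L   # Devescovina
  lin <- lineage(dev, tax)
  expect_true(200L %in% lin)                   # Cristamonadida
  expect_true(2611341L %in% lin)               # Metamonada
  expect_true(85823L %in% lineage(10101L, tax))  # termite species in host
  # Blattamonas sits under Oxymonadida
  expect_true(210L %in% lineage(212L, tax))
  # exactly one root
  expect_equal(sum(tax$taxid == tax$parent), 1)
  # orders resolvable by rank
  expect_identical(ancestor_at_rank(21101L, "order", tax), 210L)
})

test_that("simulate_truth: determinism, degenerate fraction, proportions", {
  cfg <- sim_config(seed = 5)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$transcripts, t2$transcripts)
  expect_identical(t1$coupled_pairs, t2$coupled_pairs)

  t0 <- simulate_truth(sim_config(seed = 5, frac_de = 0))
  expect_true(all(t0$transcripts$planted_lfc == 0))

  # every transcript gets exactly one source; counts match config
  expect_equal(unname(table(t1$transcripts$true_source)[
    c("termite", "flagellate", "unclear")]),
    c(cfg$n_termite, cfg$n_flagellate, cfg$n_unclear),
    ignore_attr = TRUE)

  # tier proportions consistent with the configured multinomial
  cfg_big <- sim_config(seed = 6, n_flagellate = 433, n_termite = 0,
                        n_unclear = 50, n_coupled_pairs = 0)
  tb <- simulate_truth(cfg_big)
  tiers <- table(factor(tb$transcripts$tier,
                        levels = names(cfg_big$flagellate_tier_probs)))
  chi <- chisq.test(tiers, p = cfg_big$flagellate_tier_probs)
  expect_gt(chi$p.value, 0.001)

  # error when coupling demands more transcripts than exist
  expect_error(simulate_truth(sim_config(n_flagellate = 4,
                                         n_coupled_pairs = 500)),
               "exceeds")
})

test_that("simulate_counts: moments, planted ratios, exchangeability", {
  # Poisson limit: dispersion ~ 0, no effects -> variance tracks the mean
  cfg <- sim_config(seed = 8, n_termite = 400, n_flagellate = 0,
                    n_unclear = 0, frac_de = 0, dispersion = 1e-13,
                    dispersion_sdlog = 0, n_coupled_pairs = 0,
                    libsize_range = c(1e6, 1e6))
  truth <- simulate_truth(cfg)
  cm <- simulate_counts(truth, cfg)
  x <- cm$counts
  vm <- apply(x, 1, var) / pmax(rowMeans(x), 1)
  keep <- rowMeans(x) > 50
  expect_gt(sum(keep), 50)
  expect_lt(abs(median(vm[keep]) - 1), 0.35)

  # planted +2 log2 fold change: soldier/worker mean ratio near 4
  cfg2 <- sim_config(seed = 9, n_termite = 400, n_flagellate = 0,
                     n_unclear = 0, frac_de = 0.02, lfc_mean = 2,
                     lfc_sd = 0, dispersion = 0.05, dispersion_sdlog = 0,
                     n_coupled_pairs = 0, libsize_range = c(1e6, 1e6))
  truth2 <- simulate_truth(cfg2)
  cm2 <- simulate_counts(truth2, cfg2)
  up <- truth2$transcripts$planted_lfc > 0
  sm <- rowMeans(cm2$counts[, cm2$caste == "soldier"])
  wm <- rowMeans(cm2$counts[, cm2$caste == "worker"])
  ratios <- sm[up] / wm[up]
  expect_gt(length(ratios), 2)
  expect_lt(abs(mean(log2(ratios)) - 2), 0.4)

  # caste exchangeability without effects: group means indistinguishable
  expect_lt(abs(mean(log2(pmax(sm[!up], 0.5) / pmax(wm[!up], 0.5)))), 0.1)

  # library sizes near the configured range under a no-effect config
  cfg3 <- sim_config(seed = 10, frac_de = 0, n_coupled_pairs = 0,
                     dispersion = 0.05, dispersion_sdlog = 0)
  cm3 <- simulate_counts(simulate_truth(cfg3), cfg3)
  ls <- colSums(cm3$counts)
  expect_true(all(ls > 0.85 * cfg3$libsize_range[1]))
  expect_true(all(ls < 1.15 * cfg3$libsize_range[2]))
})

test_that("simulate_hits respects construction guarantees", {
  cfg <- sim_config(seed = 12, decoy_rate = 0.25)
  tax <- generate_taxonomy(cfg)
  truth <- simulate_truth(cfg)
  hits <- simulate_hits(truth, tax, cfg)
  tr <- truth$transcripts

  expect_true(all(hits$qstart <= hits$qend))
  expect_true(all(hits$pident >= 0 & hits$pident <= 100))

  # genus-resolvable flagellates: five Metamonada hits all above 90
  gen_ids <- tr$id[tr$true_source == "flagellate" & tr$tier == "genus" &
                     !tr$decoyed]
  for (id in gen_ids) {
    h <- hits[hits$qseqid == id, ]
    expect_equal(nrow(h), 5)
    expect_true(all(h$pident > 90))
    expect_true(all(vapply(h$staxid, in_clade, logical(1),
                           clade_taxid = 2611341L, tax = tax)))
  }

  # conflict-mode unclear transcripts carry an outgroup hit extending
  # beyond the best-hit region by more than the default tolerance
  conf_ids <- tr$id[tr$true_source == "unclear" &
                      tr$unclear_mode == "conflict"]
  for (id in conf_ids[seq_len(min(10, length(conf_ids)))]) {
    h <- hits[hits$qseqid == id, ]
    og <- h[!vapply(h$staxid, function(s)
      in_clade(s, 2611341L, tax) || in_clade(s, 85823L, tax), logical(1)), ]
    expect_gt(nrow(og), 0)
    best <- best_hit(h)
    expect_gt(max(og$qend) - max(h$qend[h$sseqid == best$sseqid]), 30)
  }

  # all emitted sub-threshold hits exceed the parse cutoff, others pass it
  sub_ids <- tr$id[tr$true_source == "unclear" &
                     tr$unclear_mode == "subthreshold"]
  expect_true(all(hits$evalue[hits$qseqid %in% sub_ids] > 1e-5))
  expect_true(all(hits$evalue[!hits$qseqid %in% sub_ids] <= 1e-5))
})

test_that("noise-free bundles are classified perfectly end to end", {
  cfg <- sim_config(seed = 14, decoy_rate = 0)
  tax <- generate_taxonomy(cfg)
  truth <- simulate_truth(cfg)
  hits <- simulate_hits(truth, tax, cfg)
  tf <- write_hits_file(hits)
  calls <- classify_transcripts(parse_hits(tf), tax,
                                all_ids = truth$transcripts$id)
  tr <- truth$transcripts
  m <- calls[match(tr$id, calls$transcript), ]
  expect_equal(mean(m$source == tr$true_source), 1)
  fl <- tr$true_source == "flagellate"
  same_na <- function(a, b) ifelse(is.na(a), is.na(b), !is.na(b) & a == b)
  expect_true(all(same_na(tr$order[fl], m$order[fl])))
  expect_true(all(same_na(tr$genus[fl], m$genus[fl])))
})

test_that("fixture bundles round-trip and are byte-identical per seed", {
  cfg <- sim_config(seed = 15, n_termite = 60, n_flagellate = 20,
                    n_unclear = 20, n_coupled_pairs = 9,
                    fl_per_factor = 3, other_per_factor = 3)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_fixture_bundle(cfg, d1)
  p2 <- write_fixture_bundle(cfg, d2)
  expect_length(p1, 6)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     label = paste("bundle file", k))
  }
  # re-readable by the module parsers
  tax <- load_taxonomy(p1[["taxonomy"]])
  cm <- read_counts(p1[["counts"]], p1[["castes"]])
  expect_equal(dim(cm$counts), c(100, 20))
  hm <- parse_hits(p1[["hits"]])
  expect_gt(length(hm), 0)
  ann <- read_annotations(p1[["go"]])
  expect_gt(length(ann), 0)
  truth_json <- jsonlite::read_json(p1[["truth"]], simplifyVector = TRUE)
  expect_equal(length(truth_json$transcripts$id), 100)

  # counts round-trip exactly
  obj <- attr(p1, "objects")
  expect_equal(cm$counts, obj$counts$counts)

  # empty config: valid headers, zero data rows
  cfg0 <- sim_config(n_termite = 0, n_flagellate = 0, n_unclear = 0,
                     n_coupled_pairs = 0, frac_de = 0)
  d0 <- tempfile()
  p0 <- write_fixture_bundle(cfg0, d0)
  expect_equal(nrow(utils::read.delim(p0[["counts"]])), 0)
  expect_length(parse_hits(p0[["hits"]]), 0)
})
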