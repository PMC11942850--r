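test_that("correlation matrix basics and constant handling", {
  set.seed(3)
  m <- matrix(rexp(10 * 8, 0.01), 10, 8,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:8)))
  m[3, ] <- 100                      # constant transcript
  cc <- correlation_matrix(m)
  expect_equal(diag(cc), rep(1, 10), ignore_attr = TRUE)
  expect_true(all(cc[3, -3] == 0))
  expect_true(attr(cc, "constant")[3])
  # affine invariance on the transformed scale
  x <- log2(m[1, ] + 1)
  m2 <- rbind(m, aff = 2^(2 * x + 5) - 1)
  cc2 <- correlation_matrix(m2)
  expect_equal(cc2["t1", "aff"], 1, tolerance = 1e-12)
  # textbook formula by loop
  cc_none <- correlation_matrix(m, transform = "none")
  for (i in 1:3) for (j in 1:3) {
    xi <- m[i, ]; xj <- m[j, ]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    if (i == 3 || j == 3) r <- ifelse(i == j, 1, 0)
    expect_equal(cc_none[i, j], r, tolerance = 1e-12)
  }
  expect_error(correlation_matrix(m[, 1:2]), "3 samples")
})

test_that("soft adjacency powers correlations and zeroes the diagonal", {
  cc <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  a <- soft_adjacency(cc, beta = 12)
  expect_equal(a[1, 2], 0.5^12)
  expect_equal(diag(a), c(0, 0))
  expect_equal(soft_adjacency(cc, beta = 1)[1, 2], 0.5)
  expect_error(soft_adjacency(cc, beta = 0), "positive")
  # monotonicity: larger beta weakly shrinks sub-unit entries
  set.seed(4)
  cc_r <- stats::cor(matrix(rnorm(50), 10, 5))
  a6 <- soft_adjacency(cc_r, 6); a12 <- soft_adjacency(cc_r, 12)
  expect_true(all(a12 <= a6 + 1e-15))
})

test_that("topological overlap matches hand and brute-force oracles", {
  # two nodes, full adjacency
  a2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(topological_overlap(a2)[1, 2], 1)
  # zero adjacency
  a0 <- matrix(0, 4, 4)
  expect_true(all(topological_overlap(a0)[upper.tri(a0)] == 0))
  # random networks vs triple-loop brute force; entries stay in [0, 1]
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2; diag(a) <- 0
    tom <- topological_overlap(a)
    expect_equal(tom, brute_tom(a), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("consensus TOM: quantile scaling then element-wise minimum", {
  set.seed(6)
  n <- 6
  a <- matrix(runif(n * n, 0.1, 0.9), n, n); a <- (a + t(a)) / 2
  diag(a) <- 0
  t1 <- topological_overlap(a)
  t2 <- t1^1.3                       # systematically weaker network
  cons <- consensus_tom(t1, t2, scale_quantile = 0.9)
  # identical inputs: consensus equals the input
  expect_equal(consensus_tom(t1, t1), t1, tolerance = 1e-12)
  # min property against the scaled second matrix
  t2s <- scale_tom(t2, t1, 0.9)
  expect_true(all(cons <= pmin(t1, t2s) + 1e-12))
  # hand evaluation of the power transform on a 4-node case
  m1 <- matrix(c(1, .6, .2, .1,  .6, 1, .3, .2,  .2, .3, 1, .4,
                 .1, .2, .4, 1), 4, 4)
  m2 <- m1^2
  q1 <- quantile(m1[upper.tri(m1)], 0.95, names = FALSE)
  q2 <- quantile(m2[upper.tri(m2)], 0.95, names = FALSE)
  expected <- pmin(m1, m2^(log(q1) / log(q2)))
  diag(expected) <- 1
  expect_equal(consensus_tom(m1, m2), expected, tolerance = 1e-12)
})

test_that("module detection recovers planted blocks; degenerate cases", {
  n <- 30
  tom <- matrix(0.01, n, n)
  tom[1:15, 1:15] <- 0.8
  tom[16:30, 16:30] <- 0.8
  diag(tom) <- 1
  rownames(tom) <- colnames(tom) <- paste0("t", 1:n)
  mods <- detect_modules(tom, cut_height = 0.5, min_size = 10)
  expect_equal(length(unique(mods)), 2)
  expect_equal(length(unique(mods[1:15])), 1)
  expect_equal(length(unique(mods[16:30])), 1)
  # all-zero TOM at default cut: a single giant cluster would need
  # dissimilarity below the cut; with min_size > n everything is grey
  expect_true(all(detect_modules(tom, min_size = n + 1) == 0))
})

test_that("strong pairs: inclusive threshold, classes, permutations", {
  ids <- c("fA", "fB", "tC", "uD")
  w <- matrix(0, 4, 4, dimnames = list(ids, ids))
  w["fA", "tC"] <- w["tC", "fA"] <- 0.5      # exactly at threshold
  w["fA", "uD"] <- w["uD", "fA"] <- 0.7
  w["fA", "fB"] <- w["fB", "fA"] <- 0.9      # flagellate-flagellate
  w["tC", "uD"] <- w["uD", "tC"] <- 0.9      # no flagellate member
  diag(w) <- 1
  calls <- data.frame(transcript = ids,
                      source = c("flagellate", "flagellate", "termite",
                                 "unclear"),
                      order = c("OrdA", NA, NA, NA), genus = NA,
                      best_sseqid = NA, best_pident = NA, rule = "t")
  class(calls) <- c("source_calls", "data.frame")
  pairs <- strong_pairs(w, calls, threshold = 0.5)
  key <- paste(pairs$flagellate, pairs$partner)
  expect_setequal(key, c("fA tC", "fA uD", "fA fB"))
  expect_equal(pairs$weight[pairs$partner == "tC"], 0.5)  # inclusive
  expect_identical(sort(unique(pairs$partner_class)),
                   c("flagellate-unclassified", "termite", "unclear"))

  # below threshold excluded
  expect_equal(nrow(strong_pairs(w, calls, threshold = 0.95)), 0)

  # no flagellate calls -> empty
  calls2 <- calls; calls2$source <- "termite"
  class(calls2) <- c("source_calls", "data.frame")
  expect_equal(nrow(strong_pairs(w, calls2)), 0)

  # node-order permutation leaves the pair set unchanged
  perm <- c(3, 1, 4, 2)
  pairs_p <- strong_pairs(w[perm, perm], calls)
  expect_setequal(paste(pairs_p$flagellate, pairs_p$partner), key)
})

test_that("shared pairs intersect on unordered id pairs", {
  wp <- data.frame(flagellate = c("f1", "f2"), partner = c("a", "b"),
                   partner_class = "termite", weight = c(0.9, 0.8))
  sp <- data.frame(flagellate = "f1", partner = "a",
                   partner_class = "termite", weight = 0.6)
  sh <- shared_pairs(wp, sp)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$weight_worker, 0.9)
  expect_equal(sh$weight_soldier, 0.6)
  expect_equal(nrow(shared_pairs(wp, sp[0, ])), 0)
})

test_that("worker coupling yields strong pairs that soldier lacks", {
  cfg <- sim_config(seed = 61, frac_de = 0)
  truth <- simulate_truth(cfg)
  cm <- simulate_counts(truth, cfg)
  filt <- filter_low_expression(cm)
  tmm <- tmm_normalize(filt)
  calls <- calls_from_truth(truth)
  net <- build_caste_networks(tmm)
  pw <- strong_pairs(net$weight_worker, calls)
  ps <- strong_pairs(net$weight_soldier, calls)
  expect_gt(nrow(pw), nrow(ps))
  # every soldier strong pair must also be strong in workers
  if (nrow(ps) > 0)
    expect_equal(nrow(shared_pairs(pw, ps)), nrow(ps))
  # every recovered pair joins two members of the same latent factor
  # (flagellate-flagellate pairs within a factor are legitimate extras
  # beyond the listed flagellate-other truth pairs)
  fac <- truth$transcripts$factor
  names(fac) <- truth$transcripts$id
  same_factor <- !is.na(fac[pw$flagellate]) &
    fac[pw$flagellate] == fac[pw$partner]
  expect_gt(mean(same_factor), 0.95)
  # and a sizeable share of the planted truth pairs is recovered (the
  # realized spread of a latent factor over 10 samples varies by seed,
  # so per-pair recovery is noisy even when the asymmetry is clear)
  planted <- paste(truth$coupled_pairs$flagellate,
                   truth$coupled_pairs$partner)
  found <- c(paste(pw$flagellate, pw$partner),
             paste(pw$partner, pw$flagellate))
  expect_gt(mean(planted %in% found), 0.25)
})
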