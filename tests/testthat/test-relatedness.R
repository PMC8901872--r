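test_that("Queller-Goodnight matches the hand-computed single-locus value", {
  # genotypes (A,B) and (A,C); freqs A = 0.5, B = C = 0.25.
  # Reference (A,B): numerator 0.5*(1+0+0+0) - 0.75 = -0.25,
  # denominator 1 + 0 - 0.75 = 0.25 -> -1; the (A,C) direction is
  # symmetric, so r = -1.
  fr <- structure(list(loci = "L1",
                       freqs = list(L1 = c(`1` = 0.5, `2` = 0.25,
                                           `3` = 0.25)),
                       n_typed = c(L1 = 100L)), class = "allele_freqs")
  tab <- dyad_table(rbind(1L, 2L), rbind(1L, 3L), "L1")
  expect_equal(qg_estimator(tab, "A", "B", freqs = fr), -1)
})

test_that("moment estimators are mean-calibrated on simulated kinship", {
  sim <- simulate_dyads(equifreq(12, 6), n_per_category = 1000, seed = 301)
  est <- kinmate:::est_dyads(sim$table, sim$dyads, c("qg", "wang"),
                             freqs = sim$freqs)
  for (e in c("qg", "wang")) {
    mu <- tapply(est[[e]], sim$dyads$category, mean)
    expect_lt(abs(mu[["UR"]] - 0), 0.02)
    expect_lt(abs(mu[["PO"]] - 0.5), 0.02)
    expect_lt(abs(mu[["FS"]] - 0.5), 0.02)
    expect_lt(abs(mu[["HS"]] - 0.25), 0.02)
  }
})

test_that("likelihood estimators: boundary identity, bounds, known biases", {
  # disjoint alleles at every locus force the unrelated corner; there the
  # likelihood is the product of independent genotype-pair probabilities
  fr <- equifreq(4, 6)
  ga <- matrix(c(1L, 2L), 2, 4)
  gb <- matrix(c(3L, 4L), 2, 4)
  codes <- as.integer(names(fr$freqs[[1]]))
  tab <- dyad_table(matrix(codes[ga], 2, 4), matrix(codes[gb], 2, 4),
                    fr$loci)
  fit <- dyadml_estimator(tab, "A", "B", freqs = fr)
  expect_equal(fit$r, 0)
  expect_equal(fit$k0, 1)
  # independent evaluation of the unrelated log-likelihood
  ll0 <- 4 * log((2 / 36) * (2 / 36))
  idx <- kinmate:::index_alleles(tab, fr)
  cppfit <- kinmate:::.ml_dyads_cpp(idx$i1[1, , drop = FALSE],
                                    idx$i2[1, , drop = FALSE],
                                    idx$i1[2, , drop = FALSE],
                                    idx$i2[2, , drop = FALSE],
                                    lapply(fr$freqs, unname))
  expect_equal(cppfit$loglik, ll0, tolerance = 1e-10)

  # ML estimates live on [0, 1] and pick up kinship signal
  sim <- simulate_dyads(equifreq(12, 6), n_per_category = 300, seed = 17)
  est <- kinmate:::est_dyads(sim$table, sim$dyads, "dyadml",
                             freqs = sim$freqs)
  expect_true(all(est$dyadml >= 0 & est$dyadml <= 1))
  mu <- tapply(est$dyadml, sim$dyads$category, mean)
  expect_lt(abs(mu[["PO"]] - 0.5), 0.03)
  expect_lt(abs(mu[["FS"]] - 0.5), 0.03)
  expect_lt(abs(mu[["HS"]] - 0.25), 0.03)
  # truncation at the k0 boundary biases unrelated dyads upward; the bias
  # is real but bounded
  expect_gte(mu[["UR"]], 0)
  expect_lt(mu[["UR"]], 0.09)
})

test_that("identical genotypes give near-maximal relatedness", {
  fr <- equifreq(12, 6)
  codes <- as.integer(names(fr$freqs[[1]]))
  g <- matrix(codes[c(1L, 2L)], 2, 12)
  tab <- dyad_table(g, g, fr$loci)
  expect_gt(wang_estimator(tab, "A", "B", freqs = fr), 0.9)
  expect_gt(dyadml_estimator(tab, "A", "B", freqs = fr)$r, 0.9)
})

test_that("triadic estimator: rare-allele identity, reference averaging", {
  # identical genotypes carrying only rare alleles (freq 0.05) at 12 loci
  p <- c(0.05, 0.05, rep(0.9 / 4, 4))
  loci <- sprintf("L%02d", 1:12)
  fr <- structure(list(
    loci = loci,
    freqs = stats::setNames(rep(list(stats::setNames(p, 101:106)), 12),
                            loci),
    n_typed = stats::setNames(rep(183L, 12), loci)), class = "allele_freqs")
  g <- matrix(c(101L, 102L), 2, 12)
  # a common-genotype individual serves as the reference pool
  pool <- genotype_table("ref", "unknown", list(integer(0)), loci,
                         matrix(105L, 1, 12), matrix(106L, 1, 12))
  tab <- dyad_table(g, g, loci)
  fit <- trioml_estimator(tab, "A", "B", freqs = fr, reference_pool = pool,
                          n_reference = 5, seed = 2)
  expect_gt(fit$r, 0.9)
  expect_true(fit$r <= 1)

  # averaging over more references shrinks the reference-draw variance
  sim <- simulate_dyads(equifreq(6, 4), n_per_category = 3, seed = 5)
  vr <- sapply(c(10, 200), function(nr) {
    reps <- sapply(1:8, function(s)
      kinmate:::est_dyads(sim$table, sim$dyads, "trioml", freqs = sim$freqs,
                          n_reference = nr, seed = 1000 + s)$trioml)
    mean(apply(reps, 1, stats::var))
  })
  expect_lte(vr[2], vr[1])
})

test_that("estimators are invariant to allele relabeling", {
  set.seed(33)
  fr <- equifreq(6, 4)
  sim <- simulate_dyads(fr, n_per_category = 10, seed = 3)
  est1 <- kinmate:::est_dyads(sim$table, sim$dyads,
                              c("qg", "wang", "dyadml"), freqs = fr)
  # relabel allele codes with an arbitrary strictly-monotone map that also
  # permutes frequency-vector order
  remap <- c(`101` = 9L, `102` = 3L, `103` = 54L, `104` = 12L)
  tab2 <- sim$table
  tab2$a1[] <- remap[as.character(tab2$a1)]
  tab2$a2[] <- remap[as.character(tab2$a2)]
  sw <- !is.na(tab2$a1) & tab2$a1 > tab2$a2
  tmp <- tab2$a1[sw]; tab2$a1[sw] <- tab2$a2[sw]; tab2$a2[sw] <- tmp
  fr2 <- fr
  for (l in seq_along(fr2$freqs))
    names(fr2$freqs[[l]]) <- remap[names(fr2$freqs[[l]])]
  est2 <- kinmate:::est_dyads(tab2, sim$dyads, c("qg", "wang", "dyadml"),
                              freqs = fr2)
  expect_equal(est1$qg, est2$qg)
  expect_equal(est1$wang, est2$wang)
  expect_equal(est1$dyadml, est2$dyadml)
})

test_that("pairwise matrices cover all dyads and respect symmetry", {
  set.seed(12)
  n <- 12
  a1 <- matrix(sample(101:106, n * 4, TRUE), n, 4)
  a2 <- matrix(sample(101:106, n * 4, TRUE), n, 4)
  tab <- genotype_table(paste0("i", 1:n), "unknown",
                        rep(list(integer(0)), n), paste0("L", 1:4), a1, a2)
  r3 <- pairwise_matrix(genotype_table(tab$ids[1:3], "unknown",
                                       rep(list(integer(0)), 3), tab$loci,
                                       a1[1:3, ], a2[1:3, ]),
                        estimators = "qg")
  expect_equal(nrow(r3), 3L)

  rm1 <- pairwise_matrix(tab, c("qg", "wang", "dyadml"))
  expect_equal(nrow(rm1), n * (n - 1) / 2)
  # permuting individual order leaves every dyad's value unchanged
  ord <- sample(n)
  tabp <- genotype_table(tab$ids[ord], "unknown",
                         rep(list(integer(0)), n), tab$loci,
                         a1[ord, ], a2[ord, ])
  rm2 <- pairwise_matrix(tabp, c("qg", "wang", "dyadml"))
  for (e in c("qg", "wang", "dyadml"))
    expect_equal(r_lookup(rm2, rm1$id_a, rm1$id_b, e), rm1[[e]])
  # lookups are order-free within a dyad
  expect_equal(r_lookup(rm1, rm1$id_b, rm1$id_a, "qg"), rm1$qg)

  # a study-sized table produces the full dyad count
  ids <- sprintf("b%03d", 1:183)
  big <- genotype_table(ids, "unknown", rep(list(integer(0)), 183),
                        "L1", matrix(sample(101:106, 183, TRUE)),
                        matrix(sample(101:106, 183, TRUE)))
  expect_equal(nrow(pairwise_matrix(big, "qg")), 16653L)
})

test_that("dyads with missing loci are counted and flagged", {
  fr <- equifreq(8, 4)
  codes <- as.integer(names(fr$freqs[[1]]))
  ga <- matrix(codes[c(1L, 2L)], 2, 8)
  gb <- matrix(codes[c(1L, 3L)], 2, 8)
  tab <- dyad_table(ga, gb, fr$loci)
  tab$a1[2, 1:4] <- NA; tab$a2[2, 1:4] <- NA
  rm <- pairwise_matrix(tab, c("qg", "dyadml"), freqs = fr)
  expect_equal(rm$loci_used, 4L)
  expect_true(rm$low_confidence)
  # no usable loci at all -> flagged missing value, matrix not aborted
  tab$a1[2, ] <- NA; tab$a2[2, ] <- NA
  rm0 <- pairwise_matrix(tab, "qg", freqs = fr)
  expect_equal(rm0$loci_used, 0L)
  expect_true(is.na(rm0$qg))
})
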