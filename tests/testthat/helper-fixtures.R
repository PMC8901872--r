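# shared fixtures and independent oracles (kept free of the package's own
# likelihood code paths)

equifreq <- function(L = 12L, K = 6L, n_typed = 183L) {
  loci <- sprintf("L%02d", seq_len(L))
  structure(list(
    loci = loci,
    freqs = stats::setNames(
      rep(list(stats::setNames(rep(1 / K, K), 100L + seq_len(K))), L), loci),
    n_typed = stats::setNames(rep(as.integer(n_typed), L), loci)),
    class = "allele_freqs")
}

# genotype_table holding one dyad given allele-code matrices (2 x L each)
dyad_table <- function(ga, gb, loci = sprintf("L%02d", seq_len(ncol(ga)))) {
  genotype_table(c("A", "B"), "unknown",
                 list(integer(0), integer(0)), loci,
                 rbind(ga[1, ], gb[1, ]), rbind(ga[2, ], gb[2, ]))
}

# independent genotype-pair IBD-mode probabilities by enumeration of gene
# assignments (never calls the package's compiled code)
oracle_mode_probs <- function(g1, g2, p) {
  gp <- function(g) if (g[1] == g[2]) p[g[1]]^2 else 2 * p[g[1]] * p[g[2]]
  P0 <- gp(g1) * gp(g2)
  s <- 0
  for (i in 1:2) for (j in 1:2)
    if (g1[i] == g2[j]) s <- s + p[g1[i]] * p[g1[3 - i]] * p[g2[3 - j]]
  hom <- (g1[1] == g1[2]) + (g2[1] == g2[2])
  P1 <- s / 2^hom
  P2 <- if (identical(sort(g1), sort(g2))) gp(g1) else 0
  c(P0, P1, P2)
}

# 0.001-step grid-search maximizer over the (k0, k1, k2) simplex; ties within
# 1e-9 broken toward larger k0, mirroring the documented convention
oracle_grid_ml <- function(Pmat, step = 0.001) {
  best_ll <- -Inf
  best <- c(1, 0, 0)
  for (a in seq(0, 1, step)) {
    k2 <- seq(0, 1 - a, step)
    K <- cbind(1 - a - k2, a, k2)
    ll <- rowSums(matrix(log(K %*% t(Pmat)), nrow = nrow(K)))
    i <- which.max(ll)
    if (!length(i) || !is.finite(ll[i])) next
    if (ll[i] > best_ll + 1e-9) {
      best_ll <- ll[i]; best <- K[i, ]
    } else if (ll[i] > best_ll - 1e-9 && K[i, 1] > best[1]) {
      best <- K[i, ]
    }
  }
  c(r = unname(best[3] + best[2] / 2), ll = best_ll)
}

# random 1-2 locus dyad instance for oracle-equivalence checks
random_ml_instance <- function() {
  L <- sample(1:2, 1)
  Ks <- sample(2:6, L, replace = TRUE)
  fl <- lapply(Ks, function(K) {
    x <- stats::rgamma(K, 1)
    stats::setNames(x / sum(x), 100L + seq_len(K))
  })
  loci <- paste0("L", seq_len(L))
  fr <- structure(list(loci = loci, freqs = stats::setNames(fl, loci),
                       n_typed = stats::setNames(rep(100L, L), loci)),
                  class = "allele_freqs")
  draw <- function() vapply(seq_len(L), function(l)
    as.integer(names(fl[[l]]))[sample(Ks[l], 1, prob = fl[[l]])], 0L)
  list(fr = fr, ga = rbind(draw(), draw()), gb = rbind(draw(), draw()))
}

# exact HWE test p-value for a biallelic locus by enumerating heterozygote
# counts conditional on the allele counts
oracle_hwe_exact_2allele <- function(a1, a2) {
  n <- length(a1)
  al <- c(a1, a2)
  codes <- sort(unique(al))
  stopifnot(length(codes) == 2L)
  nA <- sum(al == codes[1])
  nB <- 2L * n - nA
  hets <- seq(nA %% 2L, min(nA, nB), by = 2L)
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2; nbb <- (nB - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs_h <- sum(a1 != a2)
  sum(pr[pr <= pr[match(obs_h, hets)] + 1e-12])
}

# all permutations of seq_len(n) (n <= 6 in tests)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(seq_len(n)[-k][sub], nrow(sub), n - 1L),
          deparse.level = 0)
  }))
}

# exact two-sided (double-tail) p over an enumerated null
oracle_exact_p <- function(observed, nulls) {
  eps <- 1e-12
  min(1, 2 * min(mean(nulls <= observed + eps),
                 mean(nulls >= observed - eps)))
}

# desk-scale replicate population for calibration studies: deep pedigree
# (~220 unique pairs, ~15-20% of pairings between relatives) so the median
# statistic has a detectable target
replicate_config <- function(s, seed) {
  population_config(n_founders = 30L, n_years = 20L,
                    pairs_per_year = c(24L, 32L), recruitment = 0.6,
                    alleles_per_locus = 10L,
                    kin_avoidance_strength = s, seed = seed)
}

# simulate under replicate_config, redrawing the rare demographic crash
# (replicates are conditional on population persistence)
simulate_persistent <- function(s, seed) {
  pop <- NULL
  while (is.null(pop)) {
    pop <- tryCatch(simulate_population(replicate_config(s, seed)),
                    error = function(e) NULL)
    seed <- seed + 100000L
  }
  pop
}

write_genotype_csv <- function(path, lines) {
  writeLines(lines, path)
  path
}
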