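#' Monte-Carlo exact test for Hardy-Weinberg equilibrium at one locus
#'
#' Guo-Thompson style exact test: the observed genotype table's conditional
#' probability given the allele counts is compared with tables obtained by
#' shuffling the observed allele copies into random genotypes.  The p-value
#' uses the add-one correction `p = (1 + #{simulated tables with conditional
#' probability <= observed}) / (n_mc + 1)` and is therefore always positive.
#'
#' @param table a [genotype_table()].
#' @param locus locus name or index.
#' @param n_mc number of Monte-Carlo shuffles.
#' @param seed integer seed.
#' @return The p-value.  A monomorphic locus returns `p = 1` with a warning.
#' @export
hwe_exact_test <- function(table, locus, n_mc = 10000L, seed = NULL) {
  j <- if (is.character(locus)) match(locus, table$loci) else as.integer(locus)
  if (is.na(j)) stop("unknown locus: ", locus)
  a1 <- table$a1[, j]; a2 <- table$a2[, j]
  ok <- !is.na(a1)
  hwe_exact_alleles(a1[ok], a2[ok], n_mc = n_mc, seed = seed)
}

hwe_exact_alleles <- function(a1, a2, n_mc = 10000L, seed = NULL) {
  n <- length(a1)
  if (n < 2L) stop("need at least 2 non-missing genotypes")
  al <- c(a1, a2)
  codes <- sort(unique(al))
  if (length(codes) < 2L) {
    warning("monomorphic locus: HWE test has no degrees of freedom")
    return(1)
  }
  K <- length(codes)
  ai <- match(al, codes)
  # table-dependent part of the conditional log-probability:
  # h*log(2) - sum(log(n_g!))
  tab_logp <- function(g1, g2) {
    gm <- pmin(g1, g2); gM <- pmax(g1, g2)
    cnt <- tabulate((gm - 1L) * K + gM, nbins = K * K)
    sum(gm != gM) * log(2) - sum(lgamma(cnt + 1))
  }
  obs <- tab_logp(ai[seq_len(n)], ai[n + seq_len(n)])
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_mc)) {
      perm <- sample.int(2L * n)
      s1 <- ai[perm[seq_len(n)]]
      s2 <- ai[perm[n + seq_len(n)]]
      if (tab_logp(s1, s2) <= obs + 1e-9) hits <- hits + 1L
    }
    (1 + hits) / (n_mc + 1)
  })
}

#' Null-allele frequency estimates from the heterozygote deficit
#'
#' `chakraborty`: `(H_E - H_O) / (H_E + H_O)`; `brookfield1`:
#' `(H_E - H_O) / (1 + H_E)`.  Both are clipped at 0 from below; a locus with
#' `H_E = 0` returns 0.  `H_O` is the fraction of heterozygotes among typed
#' individuals and `H_E = 1 - sum(p^2)` from the sample allele frequencies.
#'
#' @param table a [genotype_table()].
#' @param locus locus name/index, or `NULL` for all loci.
#' @param method which estimator.
#' @return Named numeric vector of estimates.
#' @export
null_allele_frequency <- function(table, locus = NULL,
                                  method = c("chakraborty", "brookfield1")) {
  method <- match.arg(method)
  loci <- if (is.null(locus)) table$loci else
    table$loci[if (is.character(locus)) match(locus, table$loci) else locus]
  out <- vapply(loci, function(lc) {
    j <- match(lc, table$loci)
    ho_he <- locus_het(table, j)
    null_from_het(ho_he["H_O"], ho_he["H_E"], method)
  }, 0)
  stats::setNames(out, loci)
}

null_from_het <- function(H_O, H_E, method) {
  if (H_E <= 0) return(0)
  est <- if (method == "chakraborty") (H_E - H_O) / (H_E + H_O) else
    (H_E - H_O) / (1 + H_E)
  max(0, unname(est))
}

locus_het <- function(table, j) {
  a1 <- table$a1[, j]; a2 <- table$a2[, j]
  ok <- !is.na(a1)
  if (!any(ok)) stop("locus '", table$loci[j], "' has no typed genotypes")
  H_O <- mean(a1[ok] != a2[ok])
  p <- table(c(a1[ok], a2[ok]))
  p <- as.numeric(p) / sum(p)
  c(H_O = H_O, H_E = 1 - sum(p^2))
}

#' Probability of identity of a marker panel
#'
#' Per-locus `PID_l = 2 * (sum(p^2))^2 - sum(p^4)` (the probability that two
#' random individuals share an identical genotype at the locus under HWE),
#' multiplied across loci.
#'
#' @param freqs an [allele_frequencies()] object.
#' @param per_locus if `TRUE`, return the per-locus values instead of the
#'   product.
#' @return The across-loci PID (or per-locus named vector).
#' @export
probability_of_identity <- function(freqs, per_locus = FALSE) {
  pid <- vapply(freqs$freqs, function(p) 2 * sum(p^2)^2 - sum(p^4), 0)
  if (per_locus) pid else prod(pid)
}

#' Standardized index of association (multilocus disequilibrium)
#'
#' The index of association standardized for locus number (Agapow-Burt
#' r-bar-d): with per-locus inter-individual distances `d_l` (number of
#' allele differences between two individuals' genotypes, 0/1/2, pairs with
#' missing data at a locus excluded from that locus), the statistic is the
#' summed between-locus distance covariance divided by the sum of pairwise
#' products of per-locus distance standard deviations.  Under free
#' recombination and random association it is near 0; identical loci give 1.
#' The permutation p-value shuffles genotypes among individuals
#' independently at each locus, destroying between-locus association while
#' preserving single-locus structure.
#'
#' @param table a [genotype_table()] with at least 2 loci and 3 individuals.
#' @param n_perm number of permutations (0 skips the test).
#' @param seed integer seed.
#' @return List of class `multilocus_ld` with `rbar_d`, `p_value`, `n_perm`,
#'   `seed`.
#' @export
multilocus_rbar_d <- function(table, n_perm = 999L, seed = NULL) {
  L <- length(table$loci)
  n <- length(table$ids)
  if (L < 2L) stop("r-bar-d is undefined for a single locus")
  if (n < 3L) stop("need at least 3 individuals")
  pr <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)  # i > j pairs
  pi <- pr[, 1]; pj <- pr[, 2]
  dmat <- lapply(seq_len(L), function(l) locus_dist_matrix(table, l))
  D <- vapply(seq_len(L), function(l) dmat[[l]][cbind(pi, pj)],
              numeric(length(pi)))
  obs <- rbar_d_from_dist(D)
  p_value <- NA_real_
  if (n_perm > 0L) {
    p_value <- with_seed(seed, {
      hits <- 0L
      Dp <- D
      for (b in seq_len(n_perm)) {
        for (l in seq_len(L)) {
          perm <- sample.int(n)
          Dp[, l] <- dmat[[l]][cbind(perm[pi], perm[pj])]
        }
        if (rbar_d_from_dist(Dp) >= obs - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (n_perm + 1)
    })
  }
  structure(list(rbar_d = obs, p_value = p_value, n_perm = n_perm,
                 seed = seed), class = "multilocus_ld")
}

#' @export
print.multilocus_ld <- function(x, ...) {
  cat(sprintf("r-bar-d = %.4g (p = %s, %d permutations)\n", x$rbar_d,
              format.pval(x$p_value), x$n_perm))
  invisible(x)
}

locus_dist_matrix <- function(table, l) {
  a1 <- table$a1[, l]; a2 <- table$a2[, l]
  n <- length(a1)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    if (is.na(a1[i])) next
    sh <- shared_alleles(a1[i], a2[i], a1, a2)
    d[i, ] <- 2 - sh
  }
  d[is.na(a1), ] <- NA_real_
  d[, is.na(a1)] <- NA_real_
  d
}

rbar_d_from_dist <- function(D) {
  cv <- if (anyNA(D)) stats::cov(D, use = "pairwise.complete.obs") else
    stats::cov(D)
  v <- diag(cv)
  off <- upper.tri(cv)
  num <- sum(cv[off])
  den <- sum(sqrt(outer(v, v))[off])
  if (den <= 0) return(NA_real_)
  num / den
}

#' Per-locus marker quality-control summaries
#'
#' @param table a [genotype_table()].
#' @param n_mc Monte-Carlo shuffles for the HWE exact test.
#' @param seed integer seed (per-locus sub-seeds are derived from it).
#' @return Data frame with one row per locus: `n_typed`, `n_alleles`, `H_O`,
#'   `H_E`, `hwe_p`, `hwe_p_bonferroni` (raw p times the number of loci,
#'   capped at 1), and the two null-allele estimates.
#' @export
locus_summaries <- function(table, n_mc = 10000L, seed = NULL) {
  L <- length(table$loci)
  seeds <- make_seeds(seed, L)
  rows <- lapply(seq_len(L), function(j) {
    het <- locus_het(table, j)
    nt <- sum(!is.na(table$a1[, j]))
    na <- length(unique(stats::na.omit(c(table$a1[, j], table$a2[, j]))))
    p <- if (na < 2L) 1 else
      hwe_exact_test(table, j, n_mc = n_mc, seed = seeds[[j]])
    data.frame(locus = table$loci[j], n_typed = nt, n_alleles = na,
               H_O = unname(het["H_O"]), H_E = unname(het["H_E"]),
               hwe_p = p,
               null_chakraborty = null_from_het(het["H_O"], het["H_E"],
                                                "chakraborty"),
               null_brookfield1 = null_from_het(het["H_O"], het["H_E"],
                                                "brookfield1"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$hwe_p_bonferroni <- pmin(1, out$hwe_p * L)
  out
}

#' Full marker QC report
#'
#' Bundles [locus_summaries()] (HWE exact tests with Bonferroni adjustment,
#' observed/expected heterozygosity, null-allele estimates),
#' [multilocus_rbar_d()] and [probability_of_identity()].
#'
#' @inheritParams locus_summaries
#' @param n_perm permutations for the r-bar-d test.
#' @return List of class `qc_report` with elements `loci`, `ld`, `pid`.
#' @export
qc_report <- function(table, n_mc = 10000L, n_perm = 999L, seed = NULL) {
  seeds <- make_seeds(seed, 2L)
  loci <- locus_summaries(table, n_mc = n_mc, seed = seeds[[1]])
  ld <- multilocus_rbar_d(table, n_perm = n_perm, seed = seeds[[2]])
  pid <- probability_of_identity(allele_frequencies(table))
  structure(list(loci = loci, ld = ld, pid = pid), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC:", nrow(x$loci), "loci\n")
  cat("  HWE exact p range:", sprintf("%.3g-%.3g", min(x$loci$hwe_p),
                                      max(x$loci$hwe_p)),
      "| min Bonferroni-adjusted:",
      sprintf("%.3g", min(x$loci$hwe_p_bonferroni)), "\n")
  cat("  max null-allele estimate:",
      sprintf("%.4f", max(x$loci$null_chakraborty,
                          x$loci$null_brookfield1)), "\n")
  cat(sprintf("  r-bar-d = %.4g (p = %s)\n", x$ld$rbar_d,
              format.pval(x$ld$p_value)))
  cat(sprintf("  probability of identity = %.3g\n", x$pid))
  invisible(x)
}
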