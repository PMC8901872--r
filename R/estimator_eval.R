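EXPECTED_R <- c(PO = 0.5, FS = 0.5, HS = 0.25, UR = 0)

draw_alleles <- function(n, K, p) {
  sample.int(K, n, replace = TRUE, prob = p)
}

#' Simulate dyads of known relatedness from allele frequencies
#'
#' Generates `n_per_category` genotype pairs for each of four kinship
#' categories from the supplied allele frequencies, with no mutation and no
#' genotyping error: unrelated (UR, both genotypes independent draws),
#' parent-offspring (PO, the offspring inherits one uniformly chosen parental
#' allele per locus), full sibs (FS, each sib receives one uniformly chosen
#' allele from each of two parents) and half sibs (HS, the sibs share their
#' first parent only).  Expected relatedness is 0.5/0.5/0.25/0 for
#' PO/FS/HS/UR.
#'
#' @param freqs an [allele_frequencies()] object (typically estimated from
#'   the study sample).
#' @param n_per_category dyads per category.
#' @param seed integer seed; identical seeds reproduce identical genotypes.
#' @return List of class `simulated_dyads`: `table` (a [genotype_table()]
#'   holding both members of every dyad), `dyads` (data frame `id_a`, `id_b`,
#'   `category`), `expected_r`, `freqs`, `seed`.
#' @export
simulate_dyads <- function(freqs, n_per_category = 100L, seed = NULL) {
  if (n_per_category < 1L) stop("n_per_category must be >= 1")
  mono <- vapply(freqs$freqs, length, 0L) < 2L
  if (any(mono))
    warning("monomorphic loci are uninformative for related categories: ",
            paste(freqs$loci[mono], collapse = ", "))
  L <- length(freqs$loci)
  n <- n_per_category
  cats <- names(EXPECTED_R)
  with_seed(seed, {
    ga1 <- ga2 <- gb1 <- gb2 <- matrix(NA_integer_, 4L * n, L)
    for (l in seq_len(L)) {
      p <- unname(freqs$freqs[[l]])
      K <- length(p)
      codes <- as.integer(names(freqs$freqs[[l]]))
      for (ci in seq_along(cats)) {
        rows <- (ci - 1L) * n + seq_len(n)
        # parental gene pools
        P1 <- cbind(draw_alleles(n, K, p), draw_alleles(n, K, p))
        P2 <- cbind(draw_alleles(n, K, p), draw_alleles(n, K, p))
        P3 <- cbind(draw_alleles(n, K, p), draw_alleles(n, K, p))
        pick <- function(P) P[cbind(seq_len(n), sample(c(1L, 2L), n,
                                                       replace = TRUE))]
        g <- switch(cats[ci],
          UR = list(a = cbind(draw_alleles(n, K, p), draw_alleles(n, K, p)),
                    b = cbind(draw_alleles(n, K, p), draw_alleles(n, K, p))),
          PO = list(a = P1,
                    b = cbind(pick(P1), draw_alleles(n, K, p))),
          FS = list(a = cbind(pick(P1), pick(P2)),
                    b = cbind(pick(P1), pick(P2))),
          HS = list(a = cbind(pick(P1), pick(P2)),
                    b = cbind(pick(P1), pick(P3))))
        ga1[rows, l] <- codes[g$a[, 1]]; ga2[rows, l] <- codes[g$a[, 2]]
        gb1[rows, l] <- codes[g$b[, 1]]; gb2[rows, l] <- codes[g$b[, 2]]
      }
    }
    tag <- sprintf("%s_%04d", rep(cats, each = n), rep(seq_len(n), 4L))
    ids <- c(paste0(tag, "_a"), paste0(tag, "_b"))
    m <- length(tag)
    table <- genotype_table(ids, rep("unknown", 2L * m),
                            rep(list(integer(0)), 2L * m), freqs$loci,
                            rbind(ga1, gb1), rbind(ga2, gb2))
    dyads <- data.frame(id_a = paste0(tag, "_a"), id_b = paste0(tag, "_b"),
                        category = rep(cats, each = n),
                        stringsAsFactors = FALSE)
    structure(list(table = table, dyads = dyads, expected_r = EXPECTED_R,
                   freqs = freqs, seed = seed),
              class = "simulated_dyads")
  })
}

#' Correlation between estimated and expected relatedness
#'
#' Runs one estimator over a [simulate_dyads()] set and returns the Pearson
#' correlation between the estimates and the category expectations
#' (0.5/0.5/0.25/0), the criterion used to pick a working estimator.
#'
#' @param sim a `simulated_dyads` object.
#' @param estimator one of `"qg"`, `"wang"`, `"dyadml"`, `"trioml"`.
#' @param n_reference,seed,reference_pool passed to the triadic estimator;
#'   `reference_pool = NULL` uses the simulated individuals themselves.
#' @return Pearson correlation (scalar).
#' @export
estimator_correlation <- function(sim, estimator, n_reference = 100L,
                                  seed = NULL, reference_pool = NULL) {
  estimator <- match.arg(estimator, ESTIMATOR_ORDER)
  est <- est_dyads(sim$table, sim$dyads, estimator, freqs = sim$freqs,
                   n_reference = n_reference, seed = seed,
                   reference_pool = reference_pool)[[estimator]]
  expected <- sim$expected_r[sim$dyads$category]
  if (stats::sd(est, na.rm = TRUE) == 0 || stats::sd(expected) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(est, expected, use = "complete.obs")
}

#' Pick the working estimator by correlation
#'
#' Argmax over the supplied correlations; exact ties are broken by the fixed
#' order trioml, dyadml, wang, qg.
#'
#' @param correlations named numeric vector (names are estimator ids).
#' @return The selected estimator name.
#' @export
select_estimator <- function(correlations) {
  if (!length(correlations)) stop("empty correlation map")
  nm <- names(correlations)
  ord <- order(match(nm, ESTIMATOR_ORDER))
  correlations <- correlations[ord]
  names(correlations)[which.max(correlations)]
}
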