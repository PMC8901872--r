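#' @useDynLib kinmate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

ESTIMATOR_ORDER <- c("trioml", "dyadml", "wang", "qg")

# evaluate expr with a locally set RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# derive n reproducible sub-seeds (kept below 2^31)
make_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

# map allele codes to 1-based indices into the per-locus frequency vectors
index_alleles <- function(table, freqs) {
  L <- length(table$loci)
  i1 <- matrix(NA_integer_, nrow(table$a1), L)
  i2 <- i1
  for (l in seq_len(L)) {
    nm <- names(freqs$freqs[[l]])
    i1[, l] <- match(as.character(table$a1[, l]), nm)
    i2[, l] <- match(as.character(table$a2[, l]), nm)
  }
  miss <- is.na(i1) | is.na(i2)
  i1[miss] <- NA_integer_; i2[miss] <- NA_integer_
  list(i1 = i1, i2 = i2)
}

# multiset allele sharing (0, 1, 2) between genotype index pairs
shared_alleles <- function(a1, a2, b1, b2) {
  pmax((a1 == b1) + (a2 == b2), (a1 == b2) + (a2 == b1))
}

qg_engine <- function(ga1, ga2, gb1, gb2, fv) {
  n <- nrow(ga1)
  numx <- denx <- numy <- deny <- numeric(n)
  any_loc <- logical(n)
  for (l in seq_along(fv)) {
    p <- fv[[l]]
    if (length(p) < 2L) next
    ok <- !is.na(ga1[, l]) & !is.na(gb1[, l])
    if (!any(ok)) next
    a <- ga1[ok, l]; b <- ga2[ok, l]; c_ <- gb1[ok, l]; d <- gb2[ok, l]
    pa <- p[a]; pb <- p[b]; pc <- p[c_]; pd <- p[d]
    iac <- a == c_; iad <- a == d; ibc <- b == c_; ibd <- b == d
    sim <- 0.5 * (iac + iad + ibc + ibd)
    numx[ok] <- numx[ok] + sim - pa - pb
    denx[ok] <- denx[ok] + 1 + (a == b) - pa - pb
    numy[ok] <- numy[ok] + sim - pc - pd
    deny[ok] <- deny[ok] + 1 + (c_ == d) - pc - pd
    any_loc[ok] <- TRUE
  }
  r <- 0.5 * (numx / denx + numy / deny)
  r[!any_loc] <- NA_real_
  r
}

wang_engine <- function(ga1, ga2, gb1, gb2, fv) {
  n <- nrow(ga1)
  m11 <- m12 <- m22 <- b1v <- b2v <- numeric(n)
  any_loc <- logical(n)
  for (l in seq_along(fv)) {
    p <- fv[[l]]
    if (length(p) < 2L) next
    a2s <- sum(p^2); a3s <- sum(p^3); a4s <- sum(p^4)
    # expected similarity-category probabilities under pure IBD modes
    P0 <- c(2 * a2s^2 - a4s, 4 * (a3s - a4s),
            4 * (a2s - a2s^2 - 2 * a3s + 2 * a4s))
    P1 <- c(a2s, 2 * (a2s - a3s), 1 - 3 * a2s + 2 * a3s)
    P2 <- c(1, 0, 0)
    X <- cbind(P1 - P0, P2 - P0)
    w <- 1 / (2 * a2s - a3s)
    ok <- !is.na(ga1[, l]) & !is.na(gb1[, l])
    if (!any(ok)) next
    a <- ga1[ok, l]; b <- ga2[ok, l]; c_ <- gb1[ok, l]; d <- gb2[ok, l]
    sh <- shared_alleles(a, b, c_, d)
    homA <- a == b; homB <- c_ == d
    y1 <- as.numeric(sh == 2L)
    y2 <- as.numeric(sh == 1L & xor(homA, homB))
    y3 <- as.numeric(sh == 1L & !homA & !homB)
    r1 <- y1 - P0[1]; r2 <- y2 - P0[2]; r3 <- y3 - P0[3]
    b1v[ok] <- b1v[ok] + w * (X[1, 1] * r1 + X[2, 1] * r2 + X[3, 1] * r3)
    b2v[ok] <- b2v[ok] + w * (X[1, 2] * r1 + X[2, 2] * r2 + X[3, 2] * r3)
    m11[ok] <- m11[ok] + w * sum(X[, 1]^2)
    m12[ok] <- m12[ok] + w * sum(X[, 1] * X[, 2])
    m22[ok] <- m22[ok] + w * sum(X[, 2]^2)
    any_loc[ok] <- TRUE
  }
  det <- m11 * m22 - m12^2
  k1 <- (b1v * m22 - b2v * m12) / det
  k2 <- (m11 * b2v - m12 * b1v) / det
  r <- k2 + 0.5 * k1
  r[!any_loc | abs(det) < 1e-12] <- NA_real_
  r
}

sample_references <- function(pool_idx, n_reference, mode, freqs, seed) {
  with_seed(seed, {
    if (mode == "synthetic") {
      L <- length(freqs$freqs)
      ra1 <- matrix(NA_integer_, n_reference, L)
      ra2 <- ra1
      for (l in seq_len(L)) {
        K <- length(freqs$freqs[[l]])
        ra1[, l] <- sample.int(K, n_reference, replace = TRUE,
                               prob = freqs$freqs[[l]])
        ra2[, l] <- sample.int(K, n_reference, replace = TRUE,
                               prob = freqs$freqs[[l]])
      }
      return(list(a1 = ra1, a2 = ra2))
    }
    npool <- nrow(pool_idx$i1)
    usable <- which(rowSums(!is.na(pool_idx$i1)) > 0L)
    if (!length(usable)) stop("reference pool has no usable individuals")
    rows <- sample(usable, n_reference, replace = TRUE)
    list(a1 = pool_idx$i1[rows, , drop = FALSE],
         a2 = pool_idx$i2[rows, , drop = FALSE])
  })
}

# shared dyad-estimation engine; dyads is a data.frame with id_a, id_b
est_dyads <- function(table, dyads, estimators, freqs = NULL,
                      n_reference = 500L, seed = NULL,
                      reference_pool = NULL,
                      reference_mode = c("observed", "synthetic")) {
  reference_mode <- match.arg(reference_mode)
  estimators <- match.arg(estimators, ESTIMATOR_ORDER, several.ok = TRUE)
  if (is.null(freqs)) freqs <- allele_frequencies(table)
  idx <- index_alleles(table, freqs)
  ia <- match(as.character(dyads$id_a), table$ids)
  ib <- match(as.character(dyads$id_b), table$ids)
  if (anyNA(ia) || anyNA(ib)) stop("dyad ids not found in genotype table")
  ga1 <- idx$i1[ia, , drop = FALSE]; ga2 <- idx$i2[ia, , drop = FALSE]
  gb1 <- idx$i1[ib, , drop = FALSE]; gb2 <- idx$i2[ib, , drop = FALSE]
  fv <- lapply(freqs$freqs, unname)
  out <- data.frame(id_a = as.character(dyads$id_a),
                    id_b = as.character(dyads$id_b),
                    loci_used = rowSums(!is.na(ga1) & !is.na(gb1)),
                    stringsAsFactors = FALSE)
  if ("qg" %in% estimators) {
    raw <- qg_engine(ga1, ga2, gb1, gb2, fv)
    out$qg <- pmin(1, pmax(-1, raw))
    out$qg_raw <- raw
  }
  if ("wang" %in% estimators) {
    raw <- wang_engine(ga1, ga2, gb1, gb2, fv)
    out$wang <- pmin(1, pmax(-1, raw))
    out$wang_raw <- raw
  }
  if ("dyadml" %in% estimators) {
    fit <- .ml_dyads_cpp(ga1, ga2, gb1, gb2, fv)
    out$dyadml <- fit$r
    out$dyadml_k0 <- fit$k[, 1]; out$dyadml_k1 <- fit$k[, 2]
    out$dyadml_k2 <- fit$k[, 3]
  }
  if ("trioml" %in% estimators) {
    pool_idx <- if (is.null(reference_pool)) idx else
      index_alleles(reference_pool, freqs)
    refs <- sample_references(pool_idx, n_reference, reference_mode,
                              freqs, seed)
    fit <- .ml_dyads_ref_cpp(ga1, ga2, gb1, gb2, refs$a1, refs$a2, fv,
                             2 * unname(freqs$n_typed))
    out$trioml <- fit$r
    out$trioml_k0 <- fit$k[, 1]; out$trioml_k1 <- fit$k[, 2]
    out$trioml_k2 <- fit$k[, 3]
  }
  out$low_confidence <- out$loci_used < 6L
  out
}

#' Queller-Goodnight moment estimator of pairwise relatedness
#'
#' Per reference individual, the locus-wise numerator is the dyad's allele
#' sharing corrected by population allele frequencies and the denominator the
#' expected-sharing correction; numerators and denominators are summed across
#' loci before dividing, and the two reference directions are averaged.
#' Monomorphic loci and loci with missing data in either individual are
#' skipped.
#'
#' @param table a [genotype_table()].
#' @param id_a,id_b individual ids (vectors of equal length for many dyads).
#' @param freqs an [allele_frequencies()] object; computed from `table` when
#'   `NULL`.
#' @return Numeric vector of relatedness estimates (clipped to `[-1, 1]`;
#'   `NA` if no usable loci).
#' @export
qg_estimator <- function(table, id_a, id_b, freqs = NULL) {
  est_dyads(table, data.frame(id_a = id_a, id_b = id_b), "qg",
            freqs = freqs)$qg
}

#' Wang-type moment estimator of pairwise relatedness
#'
#' Method-of-moments estimator from the joint probabilities of the dyad
#' falling in the genotype-similarity categories (identical genotypes;
#' homozygote-heterozygote sharing one allele; two heterozygotes sharing one
#' allele).  Category probabilities are linear in the IBD coefficients
#' `(k1, k2)` with coefficients computed exactly from allele-frequency power
#' sums; the moment equations are solved by weighted least squares across
#' loci with per-locus weights `1 / (2*sum(p^2) - sum(p^3))`.
#'
#' @inheritParams qg_estimator
#' @return Numeric vector of relatedness estimates (clipped to `[-1, 1]`).
#' @export
wang_estimator <- function(table, id_a, id_b, freqs = NULL) {
  est_dyads(table, data.frame(id_a = id_a, id_b = id_b), "wang",
            freqs = freqs)$wang
}

#' Dyadic maximum-likelihood relatedness estimator
#'
#' Maximizes, over the IBD coefficients `(k0, k1, k2)` on the 2-simplex, the
#' product over loci of the probability of the observed genotype pair under
#' the 3-mode non-inbred IBD model.  The log-likelihood is concave in `k`, so
#' the EM fixed-point iteration used here attains the global maximum;
#' likelihood ties within 1e-8 are broken toward the unrelated boundary
#' (larger `k0`).  Relatedness is `r = k2 + k1/2`, bounded in `[0, 1]`.
#'
#' @inheritParams qg_estimator
#' @return Data frame with columns `r`, `k0`, `k1`, `k2`, `loci_used`.
#' @export
dyadml_estimator <- function(table, id_a, id_b, freqs = NULL) {
  fit <- est_dyads(table, data.frame(id_a = id_a, id_b = id_b), "dyadml",
                   freqs = freqs)
  data.frame(r = fit$dyadml, k0 = fit$dyadml_k0, k1 = fit$dyadml_k1,
             k2 = fit$dyadml_k2, loci_used = fit$loci_used)
}

#' Triadic (reference-augmented) maximum-likelihood relatedness estimator
#'
#' Extends the dyadic likelihood with a third individual used as a control
#' for identity in state: for each sampled reference individual, its two gene
#' copies per locus are added to the allele-frequency estimate
#' (counts-weighted against the `2 * n_typed` gene copies behind the
#' estimate), the dyadic likelihood is maximized under the augmented
#' frequencies, and the final estimate is the average over `n_reference`
#' seeded reference draws.  Alleles carried by a random reference thus get
#' up-weighted frequencies, discounting their evidence for IBD in the focal
#' dyad.  Estimates are bounded in `[0, 1]` by construction.
#'
#' @inheritParams qg_estimator
#' @param reference_pool genotype table to draw reference individuals from
#'   (default: `table` itself, i.e. the observed adults).
#' @param n_reference number of reference draws (with replacement).
#' @param seed integer seed for the reference draws.
#' @param reference_mode `"observed"` draws references from `reference_pool`;
#'   `"synthetic"` draws reference genotypes from the allele frequencies.
#' @return Data frame with columns `r`, `k0`, `k1`, `k2`, `loci_used`
#'   (coefficients averaged over reference draws).
#' @export
trioml_estimator <- function(table, id_a, id_b, freqs = NULL,
                             reference_pool = NULL, n_reference = 500L,
                             seed = NULL,
                             reference_mode = c("observed", "synthetic")) {
  fit <- est_dyads(table, data.frame(id_a = id_a, id_b = id_b), "trioml",
                   freqs = freqs, n_reference = n_reference, seed = seed,
                   reference_pool = reference_pool,
                   reference_mode = match.arg(reference_mode))
  data.frame(r = fit$trioml, k0 = fit$trioml_k0, k1 = fit$trioml_k1,
             k2 = fit$trioml_k2, loci_used = fit$loci_used)
}

#' Pairwise relatedness matrix over all (or selected) dyads
#'
#' Computes every unordered dyad among the table's individuals (or a supplied
#' subset of dyads) for the requested estimators.  Values are symmetric in
#' the dyad by construction and deterministic given `seed`.  Dyads with fewer
#' than 6 loci typed in both individuals are flagged `low_confidence` but
#' still reported.
#'
#' @inheritParams trioml_estimator
#' @param estimators subset of `c("qg", "wang", "dyadml", "trioml")`.
#' @param dyads optional data frame with columns `id_a`, `id_b` restricting
#'   computation to those dyads.
#' @return A data frame of class `relatedness_matrix` with columns `id_a`,
#'   `id_b`, `loci_used`, one column per estimator (moment estimators also
#'   keep an unclipped `<name>_raw` column), and `low_confidence`.
#' @export
pairwise_matrix <- function(table, estimators = ESTIMATOR_ORDER,
                            freqs = NULL, n_reference = 500L, seed = NULL,
                            reference_pool = NULL,
                            reference_mode = c("observed", "synthetic"),
                            dyads = NULL) {
  if (length(table$ids) < 2L) stop("need at least 2 individuals")
  if (is.null(dyads)) {
    cmb <- utils::combn(table$ids, 2L)
    dyads <- data.frame(id_a = cmb[1, ], id_b = cmb[2, ],
                        stringsAsFactors = FALSE)
  }
  out <- est_dyads(table, dyads, estimators, freqs = freqs,
                   n_reference = n_reference, seed = seed,
                   reference_pool = reference_pool,
                   reference_mode = match.arg(reference_mode))
  attr(out, "estimators") <- intersect(ESTIMATOR_ORDER, names(out))
  attr(out, "key") <- dyad_key(out$id_a, out$id_b)
  class(out) <- c("relatedness_matrix", "data.frame")
  out
}

dyad_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Look up relatedness values for dyads
#'
#' @param r a [pairwise_matrix()] result.
#' @param id_a,id_b id vectors (order within a dyad does not matter).
#' @param estimator estimator column to return.
#' @return Numeric vector; `NA` for dyads absent from `r`.
#' @export
r_lookup <- function(r, id_a, id_b, estimator) {
  key <- attr(r, "key")
  if (is.null(key)) key <- dyad_key(r$id_a, r$id_b)
  r[[estimator]][match(dyad_key(as.character(id_a), as.character(id_b)),
                       key)]
}
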