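#' Kinship matrix from a pedigree (tabular method)
#'
#' Recursive (tabular) kinship: founders are unrelated and non-inbred, so
#' `phi(i, i) = 0.5 * (1 + phi(sire_i, dam_i))` and
#' `phi(i, j) = 0.5 * (phi(sire_i, j) + phi(dam_i, j))` for `j` born before
#' `i`.  Individuals are processed in birth order; parents must precede
#' offspring.
#'
#' @param pedigree a `pedigree` data frame (`id`, `sire`, `dam`, `sex`,
#'   `birth_year`; founders have `NA` parents), e.g. from
#'   [simulate_population()].
#' @return Symmetric kinship matrix with ids as dimnames.
#' @export
pedigree_kinship <- function(pedigree) {
  ord <- order(pedigree$birth_year)
  ped <- pedigree[ord, , drop = FALSE]
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  if (any(!is.na(si) & si >= seq_len(n)) ||
      any(!is.na(di) & di >= seq_len(n)))
    stop("pedigree is not ordered: a parent does not precede its offspring")
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      phi[i, i] <- 0.5
    } else {
      prev <- seq_len(i - 1L)
      row <- 0.5 * (phi[si[i], prev] + phi[di[i], prev])
      phi[i, prev] <- row
      phi[prev, i] <- row
      phi[i, i] <- 0.5 * (1 + phi[si[i], di[i]])
    }
  }
  phi
}

#' Pedigree relatedness between two individuals
#'
#' `r = 2 * phi`, twice the kinship coefficient computed by the tabular
#' method ([pedigree_kinship()]).  Serves as the ground-truth oracle for the
#' marker-based estimators: parent-offspring pairs with unrelated parents
#' give 0.5, founders 0, first cousins 0.125.
#'
#' @param pedigree a `pedigree` data frame.
#' @param id_a,id_b individual ids (vectors of equal length are allowed).
#' @param kinship optional precomputed [pedigree_kinship()] matrix.
#' @return Numeric vector of relatedness values.
#' @export
pedigree_relatedness <- function(pedigree, id_a, id_b, kinship = NULL) {
  if (is.null(kinship)) kinship <- pedigree_kinship(pedigree)
  ia <- match(as.character(id_a), rownames(kinship))
  ib <- match(as.character(id_b), rownames(kinship))
  if (anyNA(ia) || anyNA(ib))
    stop("unknown id(s): ",
         paste(unique(c(id_a[is.na(ia)], id_b[is.na(ib)])), collapse = ", "))
  2 * kinship[cbind(ia, ib)]
}
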