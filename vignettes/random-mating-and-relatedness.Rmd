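---
title: "Testing random mating with respect to genetic relatedness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing random mating with respect to genetic relatedness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the inference

In a socially monogamous bird population monitored over several breeding
seasons, do individuals pair at random with respect to their genetic
relatedness?  Inbreeding-avoidance mechanisms — notably female-biased natal
dispersal, in which females settle away from their natal patch while males
are philopatric — predict that the relatedness `r` of actual breeding pairs
should be *lower* than the relatedness of pairs assembled at random from the
same birds.

`kinmate` implements this inference as a permutation test.  The test
statistic is the mean (and, in parallel, the median) of the pairwise
relatedness of the observed breeding pairs.  The null distribution is built
by repeatedly re-assigning, *within each breeding season*, the recorded
males to the recorded females uniformly at random and without replacement,
so that randomized pairs are only ever formed between birds that were
reproductively active in the same season.  Because some pairs stay together
across seasons, two conventions matter:

* **Unique pairs.** Only the first observation of each female–male
  combination enters the pooled statistics; otherwise faithful pairs would
  be over-weighted.  For the pooled test each unique pair is anchored to the
  season of its first observation and permutation runs within those year
  strata.
* **Remated pairs.** In the per-season analyses, a pair that re-forms in a
  later season is held fixed ("frozen") in every permutation replicate: its
  persistence is a consequence of mate fidelity, not of the season's pair
  formation, so re-randomizing it would test the wrong mechanism.  The
  freeze is off by default for the pooled analysis (where each combination
  appears once, in its formation year) and can be enabled with a flag.

The two-sided p-value is, by default, the *double-tail* construction
`p = min(1, 2*min(P(null <= obs), P(null >= obs)))` with the add-one
correction `(1 + count)/(B + 1)`, so `p > 0` always.  An alternative
*extremity* construction (distance from the null mean) is computed alongside
and reported whenever the two disagree by more than 0.005; on the near
symmetric null distributions of mean and median statistics the two agree
closely.

## Relatedness estimators

Relatedness is estimated from unlinked, co-dominant microsatellite
genotypes under the non-inbred dyadic IBD model: a dyad shares 0, 1 or 2
alleles identical by descent with probabilities `(k0, k1, k2)` and
`r = k2 + k1/2`.  Close inbreeding is deliberately not modeled — with a
panel of ~12 loci the 9-coefficient inbred model is not identifiable in
practice, and the populations targeted here show low frequencies of
close-kin matings.  Genotyping error is fixed at zero.  Four estimators are
provided:

* **`qg`** — the Queller–Goodnight moment estimator.  Locus numerators
  (frequency-corrected allele sharing) and denominators (expected-sharing
  correction) are summed across loci before dividing, and the two
  reference-individual directions are averaged.  Unbounded; monomorphic and
  incomplete loci are skipped.
* **`wang`** — a similarity-category moment estimator.  The dyad's genotype
  pair falls into one of four similarity categories (identical; one
  homozygote sharing with a heterozygote; two heterozygotes sharing one
  allele; no sharing), whose probabilities are linear in `(k1, k2)` with
  coefficients that are exact functions of the allele-frequency power sums
  `a2, a3, a4`.  The moment equations are solved by weighted least squares
  across loci with per-locus precision weights `1/(2*a2 - a3)`.
* **`dyadml`** — maximum likelihood over `(k0, k1, k2)` on the 2-simplex.
  The per-locus genotype-pair probability is linear in `k`, so the
  log-likelihood is concave and the EM fixed-point iteration used here
  converges to the global maximum; this is verified in the test suite
  against a 0.001-step grid search.  Estimates are bounded in `[0, 1]`.
* **`trioml`** — a triadic extension in which a third individual acts as a
  control for identity in state.  For each of `n_reference` seeded draws
  from a reference pool (by default the genotyped adults themselves), the
  reference's two gene copies per locus are added to the allele-frequency
  estimate — counts-weighted against the `2 * n_typed` gene copies behind
  it — and the dyadic likelihood is maximized under the augmented
  frequencies; the final estimate averages the draws.  Alleles carried by a
  random reference are, by construction, common alleles; up-weighting them
  discounts their evidence for IBD in the focal dyad.  This keeps the
  estimator inside the 3-parameter IBD space (so it can be audited with the
  same grid-search oracle as `dyadml`), bounded in `[0, 1]`, and its
  reference-sampling variance shrinks as `n_reference` grows.  We chose
  this construction over a full 3-individual IBD-mode likelihood: the
  triadic mode space has too many parameters to be identifiable from a
  12-locus panel, and with error rates fixed at zero a triad likelihood
  with an assumed-unrelated control factorizes and degenerates to the
  dyadic estimator.

**A bias worth knowing about.** Both likelihood estimators are truncated at
`r >= 0`.  For truly unrelated dyads roughly half the sampling distribution
of an unbounded estimator would be negative; truncation folds that mass to
zero and produces a positive mean bias of about +0.06–0.07 at 12 loci with
6 equifrequent alleles (the moment estimators are mean-unbiased to within
0.01 under the same conditions).  This is a known property of
boundary-constrained relatedness estimators, not an optimization failure —
the same estimates match the grid-search maximizer to better than `1e-3`.
It is also why the permutation machinery in the calibration studies below
uses a moment estimator: the *median* of boundary-truncated estimates is
nearly information-free when most dyads are unrelated.

**Estimator selection** mirrors standard practice: dyads of known kinship
(parent–offspring, full sib, half sib, unrelated; expected `r` 0.5, 0.5,
0.25, 0) are simulated from the observed allele frequencies, each estimator
is scored by the Pearson correlation between estimates and expectations,
and the best scorer is kept (ties broken deterministically in the order
trioml, dyadml, wang, qg).  On informative panels all four score within a
few hundredths of each other; the likelihood estimators usually lead by a
small margin.

## Marker quality control

* **Hardy–Weinberg:** a Monte-Carlo exact test (10,000 shuffles of the
  observed allele copies into genotypes by default), comparing conditional
  genotype-table probabilities, with Bonferroni adjustment across loci.
  Monomorphic loci return `p = 1` with a warning.
* **Multilocus disequilibrium:** the standardized index of association
  r̄d, computed from per-locus inter-individual distances (0, 1 or 2 allele
  differences): the summed between-locus distance covariance over the sum
  of pairwise products of per-locus distance standard deviations.
  Duplicated loci give exactly 1; independent loci give values near 0.  The
  permutation p shuffles genotypes among individuals independently at each
  locus, which destroys between-locus association while preserving each
  locus's own genotype distribution.  Note that in a pedigreed population
  r̄d is expected to be slightly positive even with free recombination —
  family structure induces identity disequilibrium — so its permutation
  test answers "is there multilocus structure?", not "is there physical
  linkage?".
* **Null alleles:** both common heterozygote-deficit estimators,
  `(H_E - H_O)/(H_E + H_O)` and `(H_E - H_O)/(1 + H_E)`, clipped at 0 and
  reported side by side (published analyses rarely say which was used).
* **Probability of identity:** per locus `2*(sum p^2)^2 - sum p^4`,
  multiplied across loci; the classic (biased) variant, which is the usual
  default in marker-panel reports.

## The synthetic population generator

Every stage of the pipeline is validated against a pedigreed
individual-based simulation (`simulate_population()`), so no field data are
required for testing.  The generator emulates the monitored system this
package targets:

| quantity | default | basis |
|---|---|---|
| breeding adults over the study | ~130–180 | study scale (~183 genotyped adults) |
| marker panel | 12 loci, 6 alleles each | study panel of 12 polymorphic microsatellites |
| seasons | 8 | study duration |
| monitored pairs per season | 12–32 | study range |
| yearly adult survival | 0.68 | published apparent-survival estimate |
| mate fidelity | 0.58 | reported pair-fidelity rate |
| age at first breeding | 1–3 yr (0.45/0.35/0.20) | >50% of recruits delay past year 1 |
| clutch size | 1–4 eggs | reported clutch range |
| egg-to-recruit probability | 0.36 | chosen for demographic stability at the above rates |
| immigration | 0 | isolated, closed population |

Founders are unrelated and drawn from the configured allele distribution;
offspring genotypes are Mendelian (no mutation, no genotyping error — the
analysis model also fixes error to zero, so injecting it would test a
different contract).  A pedigree is maintained throughout, and
`pedigree_relatedness()` (twice the tabular-method kinship coefficient) is
the ground-truth oracle against which marker-based estimates are checked.

Two optional mechanisms create non-random mating:

* **Kin avoidance:** a candidate pairing between individuals of pedigree
  relatedness `rho` is sampled with weight `exp(-s * rho)`.  `s = 0` is
  exact random mating (new pairs are uniform perfect matchings within the
  season's available singles, which is what makes the permutation null
  exact for the generator); `s = 30` effectively eliminates pairings at
  half-sib level or closer.  The weight uses *pedigree* relatedness, never
  marker estimates, so the generative truth stays independent of the
  estimators under test.
* **Female-biased dispersal:** recruiting females settle in a non-natal
  forest fragment with probability 0.9 while males stay, and pairing is
  fragment-local.  Local males are then related to each other but not to
  the immigrant females they pair with, reproducing the elevated local
  male relatedness and depressed within-pair relatedness the mechanism
  predicts.

What the generator does **not** emulate: null alleles and genotyping error,
mutation, continuous space and spatial-genetic autocorrelation surfaces
(fragments are unordered islands), extra-pair paternity, and
immigration (available behind a rate flag, default 0).  Tests passing on
synthetic data therefore validate the estimators, the permutation machinery
and the pipeline plumbing — not robustness to genotyping artifacts.

## Numerical conventions

* EM for the likelihood estimators: interior start `(1/3, 1/3, 1/3)`,
  absolute log-likelihood tolerance `1e-11`, at most 3000 iterations;
  likelihood ties within `1e-8` are resolved toward the `k0 = 1`
  (unrelated) corner so output is deterministic.
* All Monte-Carlo p-values use the add-one correction; `p` is never 0.
* Median of an even count is the midpoint average; quantiles (IQR) use
  linear interpolation (R type 7).
* A locus enters a dyad's estimate only if both individuals are typed
  there; dyads with fewer than 6 usable loci are flagged `low_confidence`
  but still reported.
* Allele frequencies are estimated from all genotyped adults pooled across
  seasons, including the focal dyad (no leave-one-out), matching common
  practice; a subset argument allows per-season estimation.
* Every stochastic routine takes an explicit integer seed; multi-stage
  routines derive sub-seeds from it reproducibly, and global RNG state is
  restored afterwards.

## Validation suite problem sizes

The test suite exercises the study conditions at sizes chosen to keep the
whole suite in the minutes range while leaving Monte-Carlo error well below
the asserted tolerances: estimator calibration uses 1,000 dyads per kinship
category at 12 loci with 6 equifrequent alleles; oracle-equivalence checks
run 50 random 1–2 locus instances against a 0.001-step grid search;
permutation exactness is checked against full enumeration at 4 and 5 pairs
with `B = 10,000`.  The type-I-error and power studies use a deep-pedigree
replicate population (30 founders, 20 seasons, 24–32 pairs per season,
recruitment 0.6, 10 alleles per locus: ~220 unique pairs of which ~15–20%
are between relatives, comparable to the ~25% related pairings of the
emulated system) with the Wang estimator and `B = 999`: 200 random-mating
replicates for size, 100 replicates at `s = 30` for power.  Replicate
datasets are drawn conditional on demographic persistence (a crashed
population — about 1–2% of seeds — is redrawn at a shifted seed).

## Known limitations

* The likelihood estimators' positive bias for unrelated dyads (above)
  means *mean* relatedness computed from `dyadml`/`trioml` over a mostly
  unrelated population sits a few hundredths above zero; comparisons
  against a permutation null are unaffected, since observed and null values
  share the bias.
* The double-tail two-sided p is conservative when the null distribution is
  strongly asymmetric; the extremity variant is reported alongside when
  they diverge.
* The permutation null conditions on the observed season strata and treats
  every within-season pairing as equally available; dispersal-distance- or
  territory-weighted nulls are out of scope.
* The GenePop reader covers the standard 2/3-digit diploid encoding only;
  sex and season metadata travel in a sidecar CSV.
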