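Package: kinmate
Title: Relatedness Estimation and Tests of Random Mating in Monitored Bird Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for asking whether social mates in a monitored, individually
    marked population pair at random with respect to genetic relatedness.
    Reads multilocus microsatellite genotype and breeding-pair tables, runs
    marker quality control (Monte-Carlo exact Hardy-Weinberg tests, the
    standardized index of association for multilocus disequilibrium,
    null-allele frequency estimates, probability of identity), computes
    pairwise relatedness by four estimators (Queller-Goodnight and Wang
    moment estimators, dyadic maximum-likelihood and reference-augmented
    triadic maximum-likelihood IBD estimators), selects an estimator by
    simulation from observed allele frequencies, and tests observed mean and
    median within-pair relatedness against a year-stratified random-mating
    permutation null with remated pairs held fixed. A pedigreed synthetic
    population generator with Mendelian inheritance and a tunable
    kin-avoidance mating bias provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
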