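#' Configuration for the synthetic study population
#'
#' Defaults emulate the monitored system the package targets: roughly 180
#' breeding adults genotyped at 12 polymorphic autosomal microsatellite loci
#' over 8 breeding seasons with 12-32 monitored pairs per season, yearly
#' adult survival of 0.68 and mate fidelity of 0.58.  The kin-avoidance
#' strength `s` down-weights a candidate pairing of pedigree relatedness
#' `rho` by `exp(-s * rho)`; `s = 0` is random mating.  Under
#' `dispersal_bias = "female_biased"`, recruiting females settle in a
#' non-natal forest fragment with probability `female_disperse_prob` while
#' males stay, and pairing is fragment-local, reproducing elevated local
#' male relatedness.
#'
#' @param n_founders founding adults (split evenly between the sexes).
#' @param n_loci,alleles_per_locus marker panel dimensions.
#' @param allele_distribution `"uniform"` founder allele frequencies, or
#'   `"dirichlet"` with concentration `dirichlet_alpha`.
#' @param dirichlet_alpha concentration parameter for `"dirichlet"`.
#' @param n_years breeding seasons simulated.
#' @param pairs_per_year integer range (length 2) of monitored pairs per
#'   season.
#' @param adult_survival yearly apparent adult survival probability.
#' @param mate_fidelity probability a surviving pair remates.
#' @param age_at_first_breeding probabilities of first breeding at ages
#'   1, 2, 3.
#' @param clutch_range integer range of eggs per clutch.
#' @param recruitment probability an egg yields a locally recruiting adult.
#' @param dispersal_bias `"none"` or `"female_biased"`.
#' @param n_fragments number of forest fragments (used when dispersal is
#'   female-biased).
#' @param female_disperse_prob probability a recruiting female leaves her
#'   natal fragment.
#' @param kin_avoidance_strength `s >= 0` in the acceptance weight
#'   `exp(-s * rho)`.
#' @param immigration_rate expected unrelated immigrant adults per year
#'   (default 0: a closed, isolated population).
#' @param start_year calendar year of the first simulated season.
#' @param seed integer seed.
#' @return List of class `population_config`.
#' @export
population_config <- function(n_founders = 110L, n_loci = 12L,
                              alleles_per_locus = 6L,
                              allele_distribution = c("uniform", "dirichlet"),
                              dirichlet_alpha = 1,
                              n_years = 8L, pairs_per_year = c(12L, 32L),
                              adult_survival = 0.68, mate_fidelity = 0.58,
                              age_at_first_breeding = c(0.45, 0.35, 0.20),
                              clutch_range = c(1L, 4L), recruitment = 0.36,
                              dispersal_bias = c("none", "female_biased"),
                              n_fragments = 5L,
                              female_disperse_prob = 0.9,
                              kin_avoidance_strength = 0,
                              immigration_rate = 0,
                              start_year = 2010L, seed = NULL) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              allele_distribution = match.arg(allele_distribution),
              dirichlet_alpha = dirichlet_alpha,
              n_years = as.integer(n_years),
              pairs_per_year = as.integer(pairs_per_year),
              adult_survival = adult_survival,
              mate_fidelity = mate_fidelity,
              age_at_first_breeding = age_at_first_breeding /
                sum(age_at_first_breeding),
              clutch_range = as.integer(clutch_range),
              recruitment = recruitment,
              dispersal_bias = match.arg(dispersal_bias),
              n_fragments = as.integer(n_fragments),
              female_disperse_prob = female_disperse_prob,
              kin_avoidance_strength = kin_avoidance_strength,
              immigration_rate = immigration_rate,
              start_year = as.integer(start_year), seed = seed)
  probs <- c(cfg$adult_survival, cfg$mate_fidelity, cfg$recruitment,
             cfg$female_disperse_prob, cfg$age_at_first_breeding)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$kin_avoidance_strength < 0)
    stop("kin_avoidance_strength must be >= 0")
  if (cfg$n_founders < 2L || cfg$n_loci < 1L || cfg$n_years < 1L)
    stop("counts must be >= 1 (and n_founders >= 2)")
  structure(cfg, class = "population_config")
}

# size-safe uniform draw from a vector (sample() would misread a scalar)
sample1 <- function(v) v[sample.int(length(v), 1L)]

#' Simulate a pedigreed, genotyped study population
#'
#' Multi-year individual-based simulation: founders carry genotypes drawn
#' from the configured allele distribution; each season, surviving pairs
#' remate with probability `mate_fidelity`, remaining mature singles form
#' new pairs (optionally fragment-local, optionally kin-biased: a candidate
#' male of pedigree relatedness `rho` to the female is sampled with weight
#' `exp(-s * rho)`), and offspring receive one uniformly chosen allele per
#' parent per locus (Mendelian, no mutation, no genotyping error).  The
#' kin-avoidance weight uses pedigree relatedness, never marker estimates,
#' so the generative truth stays independent of the estimators under test.
#'
#' @param config a [population_config()].
#' @return List of class `synthetic_population`: `table` (a
#'   [genotype_table()] of all adults that ever bred, with their breeding
#'   seasons), `pairs` (a validated `pair_records` data frame), `pedigree`
#'   (a `pedigree` data frame: `id`, `sire`, `dam`, `sex`, `birth_year`;
#'   founders have `NA` parents), `founder_freqs` (the generating allele
#'   frequencies) and `config`.
#' @export
simulate_population <- function(config) {
  cfg <- config
  with_seed(cfg$seed, {
    L <- cfg$n_loci
    K <- rep_len(cfg$alleles_per_locus, L)
    gen_p <- lapply(seq_len(L), function(l) {
      p <- if (cfg$allele_distribution == "uniform") rep(1 / K[l], K[l])
      else {
        g <- stats::rgamma(K[l], shape = cfg$dirichlet_alpha)
        g / sum(g)
      }
      stats::setNames(p, 100L + 2L * seq_len(K[l])) # even codes, msat-like
    })
    draw_geno <- function(n) {
      g1 <- matrix(NA_integer_, n, L); g2 <- g1
      for (l in seq_len(L)) {
        codes <- as.integer(names(gen_p[[l]]))
        g1[, l] <- codes[sample.int(K[l], n, TRUE, prob = gen_p[[l]])]
        g2[, l] <- codes[sample.int(K[l], n, TRUE, prob = gen_p[[l]])]
      }
      list(g1, g2)
    }

    # flat, preallocated population state; subassignments stay in place
    nF <- cfg$n_founders
    cap <- max(64L, nF * (2L + 2L * cfg$n_years))
    p_id <- character(cap); p_sex <- character(cap)
    p_sire <- rep(NA_character_, cap); p_dam <- rep(NA_character_, cap)
    p_birth <- integer(cap); p_mature <- integer(cap)
    p_frag <- integer(cap); p_alive <- logical(cap)
    phi <- matrix(0, cap, cap)
    ga1 <- matrix(NA_integer_, cap, L); ga2 <- ga1
    n_ind <- 0L

    sexes <- rep(c("female", "male"), length.out = nF)
    g <- draw_geno(nF)
    for (i in seq_len(nF)) {
      n_ind <- n_ind + 1L
      p_id[n_ind] <- sprintf("F%03d", i); p_sex[n_ind] <- sexes[i]
      p_birth[n_ind] <- cfg$start_year - 3L; p_mature[n_ind] <- 1L
      p_frag[n_ind] <- sample.int(cfg$n_fragments, 1L)
      p_alive[n_ind] <- TRUE
      phi[n_ind, n_ind] <- 0.5
    }
    ga1[seq_len(nF), ] <- g[[1]]; ga2[seq_len(nF), ] <- g[[2]]

    grow_state <- function() {  # called rarely; copies are amortized
      grow <- length(p_id)
      p_id <<- c(p_id, character(grow)); p_sex <<- c(p_sex, character(grow))
      p_sire <<- c(p_sire, rep(NA_character_, grow))
      p_dam <<- c(p_dam, rep(NA_character_, grow))
      p_birth <<- c(p_birth, integer(grow))
      p_mature <<- c(p_mature, integer(grow))
      p_frag <<- c(p_frag, integer(grow))
      p_alive <<- c(p_alive, logical(grow))
      newphi <- matrix(0, 2L * grow, 2L * grow)
      newphi[seq_len(grow), seq_len(grow)] <- phi
      phi <<- newphi
      pad <- matrix(NA_integer_, grow, L)
      ga1 <<- rbind(ga1, pad); ga2 <<- rbind(ga2, pad)
    }

    pair_rows <- vector("list", cfg$n_years)
    prev_pairs <- matrix(integer(0), 0L, 2L)  # indices (female, male)
    next_id <- 1L
    local_pairing <- cfg$dispersal_bias == "female_biased"
    s <- cfg$kin_avoidance_strength
    for (t in seq_len(cfg$n_years)) {
      year <- cfg$start_year + t - 1L
      if (t > 1L) {
        adults <- which(p_alive[seq_len(n_ind)])
        died <- adults[stats::runif(length(adults)) > cfg$adult_survival]
        p_alive[died] <- FALSE
      }
      # immigration of unrelated adults
      n_imm <- stats::rpois(1L, cfg$immigration_rate)
      if (n_imm > 0L) {
        g <- draw_geno(n_imm)
        for (i in seq_len(n_imm)) {
          if (n_ind + 1L > length(p_id)) grow_state()
          n_ind <- n_ind + 1L
          p_id[n_ind] <- sprintf("I%04d", next_id)
          next_id <- next_id + 1L
          p_sex[n_ind] <- sample(c("female", "male"), 1L)
          p_birth[n_ind] <- year - 3L; p_mature[n_ind] <- 1L
          p_frag[n_ind] <- sample.int(cfg$n_fragments, 1L)
          p_alive[n_ind] <- TRUE
          phi[n_ind, n_ind] <- 0.5
          ga1[n_ind, ] <- g[[1]][i, ]; ga2[n_ind, ] <- g[[2]][i, ]
        }
      }
      # persisting pairs
      keep <- prev_pairs[p_alive[prev_pairs[, 1]] &
                           p_alive[prev_pairs[, 2]], , drop = FALSE]
      if (nrow(keep))
        keep <- keep[stats::runif(nrow(keep)) < cfg$mate_fidelity, ,
                     drop = FALSE]
      target <- sample1(seq(cfg$pairs_per_year[1], cfg$pairs_per_year[2]))
      target <- max(target, nrow(keep))
      idx <- seq_len(n_ind)
      mature <- p_alive[idx] & (year - p_birth[idx] >= p_mature[idx])
      single <- mature & !(idx %in% c(keep))
      fem <- idx[single & p_sex[idx] == "female"]
      mal <- idx[single & p_sex[idx] == "male"]
      n_new <- min(target - nrow(keep), length(fem), length(mal))
      new_f <- integer(0); new_m <- integer(0)
      if (n_new > 0L) {
        fem <- fem[sample.int(length(fem))]
        taken <- logical(n_ind)
        for (f in fem) {
          if (length(new_f) >= n_new) break
          cand <- mal[!taken[mal]]
          if (local_pairing)
            cand <- cand[p_frag[cand] == p_frag[f]]
          if (!length(cand)) next
          w <- if (s > 0) exp(-s * 2 * phi[f, cand]) else
            rep(1, length(cand))
          m <- cand[sample.int(length(cand), 1L, prob = w)]
          taken[m] <- TRUE
          new_f <- c(new_f, f); new_m <- c(new_m, m)
        }
      }
      cur <- rbind(keep, cbind(new_f, new_m, deparse.level = 0))
      if (!nrow(cur))
        stop("infeasible configuration: no pairs could be formed in year ",
             year, " (", length(fem), " single females, ", length(mal),
             " single males)")
      pair_rows[[t]] <- data.frame(year = year,
                                   female_id = p_id[cur[, 1]],
                                   male_id = p_id[cur[, 2]],
                                   stringsAsFactors = FALSE)
      # reproduction
      for (pi in seq_len(nrow(cur))) {
        f <- cur[pi, 1]; m <- cur[pi, 2]
        clutch <- sample1(seq(cfg$clutch_range[1], cfg$clutch_range[2]))
        n_rec <- stats::rbinom(1L, clutch, cfg$recruitment)
        if (n_rec == 0L) next
        for (o in seq_len(n_rec)) {
          if (n_ind + 1L > length(p_id)) grow_state()
          sex <- if (next_id %% 2L == 0L) "female" else "male"
          frag <- p_frag[m]  # natal territory: the male's fragment
          mature_age <- sample(1:3, 1L, prob = cfg$age_at_first_breeding)
          if (cfg$dispersal_bias == "female_biased" && sex == "female" &&
              cfg$n_fragments > 1L &&
              stats::runif(1) < cfg$female_disperse_prob)
            frag <- sample1(setdiff(seq_len(cfg$n_fragments), frag))
          n_ind <- n_ind + 1L
          p_id[n_ind] <- sprintf("X%05d", next_id)
          next_id <- next_id + 1L
          p_sex[n_ind] <- sex; p_sire[n_ind] <- p_id[m]
          p_dam[n_ind] <- p_id[f]
          p_birth[n_ind] <- year; p_mature[n_ind] <- mature_age
          p_frag[n_ind] <- frag; p_alive[n_ind] <- TRUE
          prev <- seq_len(n_ind - 1L)
          krow <- 0.5 * (phi[m, prev] + phi[f, prev])
          phi[n_ind, prev] <- krow
          phi[prev, n_ind] <- krow
          phi[n_ind, n_ind] <- 0.5 * (1 + phi[m, f])
          ga1[n_ind, ] <- ifelse(stats::runif(L) < 0.5, ga1[m, ], ga2[m, ])
          ga2[n_ind, ] <- ifelse(stats::runif(L) < 0.5, ga1[f, ], ga2[f, ])
        }
      }
      prev_pairs <- cur
    }
    pairs_df <- do.call(rbind, pair_rows)
    idx <- seq_len(n_ind)
    bred <- idx[p_id[idx] %in% c(pairs_df$female_id, pairs_df$male_id)]
    yr_f <- split(pairs_df$year, pairs_df$female_id)
    yr_m <- split(pairs_df$year, pairs_df$male_id)
    years_of <- lapply(p_id[bred], function(id)
      sort(unique(c(yr_f[[id]], yr_m[[id]]))))
    table <- genotype_table(p_id[bred], p_sex[bred], years_of,
                            sprintf("loc%02d", seq_len(L)),
                            ga1[bred, , drop = FALSE],
                            ga2[bred, , drop = FALSE])
    pedigree <- structure(
      data.frame(id = p_id[idx], sire = p_sire[idx], dam = p_dam[idx],
                 sex = p_sex[idx], birth_year = p_birth[idx],
                 stringsAsFactors = FALSE),
      class = c("pedigree", "data.frame"))
    fr <- gen_p
    names(fr) <- table$loci
    founder_freqs <- structure(
      list(loci = table$loci, freqs = fr,
           n_typed = stats::setNames(rep(cfg$n_founders, L), table$loci)),
      class = "allele_freqs")
    structure(list(table = table, pairs = pair_records(pairs_df, table),
                   pedigree = pedigree, founder_freqs = founder_freqs,
                   config = cfg),
              class = "synthetic_population")
  })
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat("synthetic_population:", length(x$table$ids), "breeding adults,",
      nrow(x$pairs), "pair records over",
      length(unique(x$pairs$year)), "seasons,",
      nrow(x$pedigree), "individuals in the pedigree\n")
  invisible(x)
}
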