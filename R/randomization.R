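#' Keep the first observation of each breeding pair
#'
#' Repeatedly sampled pairs would otherwise weight the population mean and
#' median toward faithful pairs, so only the first season of each
#' female-male combination is retained.  Output is ordered by
#' `(year, female_id)`.
#'
#' @param records a `pair_records` data frame (see [pair_records()]).
#' @return The filtered `pair_records`.
#' @export
unique_pairs <- function(records) {
  out <- records[records$first_observation, , drop = FALSE]
  out <- out[order(out$year, out$female_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary statistics of within-pair relatedness
#'
#' @param pairs a `pair_records` data frame.
#' @param r a [pairwise_matrix()] result covering every pair's dyad.
#' @param estimator estimator column of `r` to summarize.
#' @return List of class `observed_pair_stats`: `n_pairs`, `mean_r`, `sd_r`,
#'   `median_r` (midpoint-average for even counts), `iqr_r` (Q3 - Q1 with
#'   linear-interpolation quantiles), proportions and counts of pairs with
#'   `r > 0.125` and `r > 0.25`, and the pair values themselves.
#' @export
observed_stats <- function(pairs, r, estimator) {
  v <- r_lookup(r, pairs$female_id, pairs$male_id, estimator)
  if (anyNA(v))
    stop("no relatedness value for pair(s): ",
         paste(sprintf("%s-%s (%d)", pairs$female_id, pairs$male_id,
                       pairs$year)[is.na(v)], collapse = ", "))
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  structure(list(
    n_pairs = length(v),
    mean_r = mean(v), sd_r = stats::sd(v),
    median_r = stats::median(v), iqr_r = q[2] - q[1],
    count_gt_0125 = sum(v > 0.125), count_gt_025 = sum(v > 0.25),
    prop_gt_0125 = mean(v > 0.125), prop_gt_025 = mean(v > 0.25),
    values = v), class = "observed_pair_stats")
}

#' @export
print.observed_pair_stats <- function(x, ...) {
  cat(sprintf(
    "%d pairs: mean r = %.3f (SD = %.2f), median r = %.3f (IQR = %.2f)\n",
    x$n_pairs, x$mean_r, x$sd_r, x$median_r, x$iqr_r))
  cat(sprintf("  r > 0.125: %d pairs (%.0f%%); r > 0.25: %d pairs (%.0f%%)\n",
              x$count_gt_0125, 100 * x$prop_gt_0125,
              x$count_gt_025, 100 * x$prop_gt_025))
  invisible(x)
}

#' Two-sided Monte-Carlo p-value
#'
#' `double_tail` (default): twice the smaller add-one-corrected tail,
#' capped at 1.  `extremity`: the add-one-corrected probability of a null
#' value at least as far from the null mean as the observed value.
#'
#' @param observed observed statistic.
#' @param null_values vector of null replicates.
#' @param method `"double_tail"` or `"extremity"`.
#' @return p-value in (0, 1].
#' @export
two_sided_p <- function(observed, null_values,
                        method = c("double_tail", "extremity")) {
  method <- match.arg(method)
  B <- length(null_values)
  if (!B) stop("empty null distribution")
  eps <- 1e-12
  if (method == "double_tail") {
    lo <- (1 + sum(null_values <= observed + eps)) / (B + 1)
    hi <- (1 + sum(null_values >= observed - eps)) / (B + 1)
    min(1, 2 * min(lo, hi))
  } else {
    ctr <- mean(null_values)
    (1 + sum(abs(null_values - ctr) >= abs(observed - ctr) - eps)) / (B + 1)
  }
}

#' Random-mating permutation null for within-pair relatedness
#'
#' Each replicate permutes, uniformly at random and without replacement,
#' the male partners among the females *within each year* (so pairs are only
#' ever formed between individuals reproductively active in the same
#' season), then recomputes the mean and median within-pair relatedness over
#' all pairs in scope.  With `respect_remated = TRUE`, pairs flagged as
#' remated are frozen: they keep their observed partner in every replicate
#' and are excluded from the permutation.  The observed statistic is
#' computed identically on the actual pairing.
#'
#' @param pairs a `pair_records` data frame (one stratum per distinct year
#'   in it).
#' @param r a [pairwise_matrix()] result containing every female x male dyad
#'   that co-occurs within a year of `pairs`.
#' @param estimator estimator column of `r`.
#' @param B number of random pairing sets.
#' @param seed integer seed.
#' @param respect_remated freeze remated pairs (used for yearly analyses).
#' @param return_assignments if `TRUE`, also return the per-replicate
#'   pairings (for auditing; memory grows with `B`).
#' @return List with elements `mean` and `median`, each of class
#'   `randomization_result`: `statistic`, `observed`, `null_values`, `B`,
#'   `seed`, `expected` (null mean), `p_two_sided` (double-tail),
#'   `p_extremity`, `scope`.
#' @export
randomize_pairings <- function(pairs, r, estimator, B = 10000L, seed = NULL,
                               respect_remated = FALSE,
                               return_assignments = FALSE) {
  if (B < 1L) stop("B must be >= 1")
  years <- sort(unique(pairs$year))
  strata <- lapply(years, function(y) {
    px <- pairs[pairs$year == y, , drop = FALSE]
    rv <- outer(seq_len(nrow(px)), seq_len(nrow(px)), function(i, j)
      r_lookup(r, px$female_id[i], px$male_id[j], estimator))
    if (anyNA(rv))
      stop("relatedness matrix is missing within-year dyads for year ", y)
    frozen <- if (respect_remated) px$remated else rep(FALSE, nrow(px))
    list(px = px, rv = rv, frozen = frozen, free = which(!frozen))
  })
  obs_vals <- unlist(lapply(strata, function(s) diag(s$rv)))
  n_pairs <- length(obs_vals)
  null_mean <- numeric(B); null_median <- numeric(B)
  assignments <- if (return_assignments) vector("list", B) else NULL
  with_seed(seed, {
    for (b in seq_len(B)) {
      vals <- numeric(0)
      asg <- if (return_assignments) vector("list", length(strata)) else NULL
      for (si in seq_along(strata)) {
        s <- strata[[si]]
        n <- nrow(s$px)
        male_of <- seq_len(n)
        nf <- length(s$free)
        if (nf > 1L) male_of[s$free] <- s$free[sample.int(nf)]
        vals <- c(vals, s$rv[cbind(seq_len(n), male_of)])
        if (return_assignments)
          asg[[si]] <- data.frame(year = s$px$year,
                                  female_id = s$px$female_id,
                                  male_id = s$px$male_id[male_of],
                                  stringsAsFactors = FALSE)
      }
      null_mean[b] <- mean(vals)
      null_median[b] <- stats::median(vals)
      if (return_assignments) assignments[[b]] <- do.call(rbind, asg)
    }
  })
  mk <- function(statistic, observed, null_values) {
    structure(list(
      statistic = statistic, observed = observed,
      null_values = null_values, B = B, seed = seed,
      expected = mean(null_values),
      p_two_sided = two_sided_p(observed, null_values, "double_tail"),
      p_extremity = two_sided_p(observed, null_values, "extremity"),
      scope = if (length(years) == 1L) paste0("year=", years) else "pooled",
      n_pairs = n_pairs), class = "randomization_result")
  }
  out <- list(mean = mk("mean", mean(obs_vals), null_mean),
              median = mk("median", stats::median(obs_vals), null_median))
  if (return_assignments) attr(out, "assignments") <- assignments
  out
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "%s (%s): observed %.4f, null expectation %.4f, p = %s (B = %d)\n",
    x$statistic, x$scope, x$observed, x$expected,
    format.pval(x$p_two_sided), x$B))
  if (abs(x$p_two_sided - x$p_extremity) > 0.005)
    cat(sprintf("  note: extremity-style two-sided p = %s\n",
                format.pval(x$p_extremity)))
  invisible(x)
}

#' Full random-mating analysis
#'
#' Runs the complete inference: filters to unique pairs, computes the
#' required relatedness values, the pooled permutation test over the unique
#' pairs (each anchored to the year of its first observation, permutation
#' within those year strata) and per-year tests over all pairs captured in
#' the year with remated pairs frozen.
#'
#' @param table a [genotype_table()].
#' @param records a `pair_records` data frame (all observed pairs).
#' @param estimator relatedness estimator to use (default `"trioml"`).
#' @param r optional precomputed [pairwise_matrix()]; computed for the
#'   needed dyads when `NULL`.
#' @param b_pooled,b_yearly replicate counts for the pooled and the yearly
#'   randomizations.
#' @param n_reference reference draws for the triadic estimator.
#' @param seed integer seed; all sub-seeds are derived from it.
#' @param respect_remated_pooled also freeze remated pairs in the pooled
#'   run (default `FALSE`; the freeze is a yearly-analysis constraint).
#' @return List of class `random_mating_report`: `observed`
#'   ([observed_stats()] over the unique pairs), `pooled` (mean and median
#'   [randomize_pairings()] results), `yearly` (per-year results),
#'   `yearly_table` (per-year observed/expected mean and median with
#'   p-values), `estimator`, `seed`, `n_unique_pairs`, `n_records`.
#' @export
run_full_analysis <- function(table, records, estimator = "trioml",
                              r = NULL, b_pooled = 10000L, b_yearly = 1000L,
                              n_reference = 500L, seed = NULL,
                              respect_remated_pooled = FALSE) {
  estimator <- match.arg(estimator, ESTIMATOR_ORDER)
  upairs <- unique_pairs(records)
  years <- sort(unique(records$year))
  if (is.null(r)) {
    need <- unique(do.call(rbind, c(
      lapply(split(upairs, upairs$year), function(px)
        expand.grid(id_a = unique(px$female_id), id_b = unique(px$male_id),
                    stringsAsFactors = FALSE)),
      lapply(split(records, records$year), function(px)
        expand.grid(id_a = unique(px$female_id), id_b = unique(px$male_id),
                    stringsAsFactors = FALSE)))))
    r <- pairwise_matrix(table, estimator, n_reference = n_reference,
                         seed = make_seeds(seed, 1L)[[1]], dyads = need)
  }
  seeds <- make_seeds(seed, 2L + length(years))
  pooled <- randomize_pairings(upairs, r, estimator, B = b_pooled,
                               seed = seeds[[2]],
                               respect_remated = respect_remated_pooled)
  yearly <- lapply(seq_along(years), function(i) {
    randomize_pairings(records[records$year == years[i], , drop = FALSE],
                       r, estimator, B = b_yearly, seed = seeds[[2 + i]],
                       respect_remated = TRUE)
  })
  names(yearly) <- years
  yearly_table <- do.call(rbind, lapply(seq_along(years), function(i) {
    ry <- yearly[[i]]
    data.frame(year = years[i], n = ry$mean$n_pairs,
               obs_mean = ry$mean$observed, exp_mean = ry$mean$expected,
               p_mean = ry$mean$p_two_sided,
               obs_median = ry$median$observed,
               exp_median = ry$median$expected,
               p_median = ry$median$p_two_sided)
  }))
  structure(list(observed = observed_stats(upairs, r, estimator),
                 pooled = pooled, yearly = yearly,
                 yearly_table = yearly_table, estimator = estimator,
                 seed = seed, n_unique_pairs = nrow(upairs),
                 n_records = nrow(records), r = r),
            class = "random_mating_report")
}

#' @export
print.random_mating_report <- function(x, ...) {
  cat(sprintf(
    "Random-mating analysis (%s estimator): %d pair records, %d unique pairs\n",
    x$estimator, x$n_records, x$n_unique_pairs))
  print(x$observed)
  cat("Pooled randomization:\n  ")
  print(x$pooled$mean)
  cat("  ")
  print(x$pooled$median)
  cat("Yearly results:\n")
  print(x$yearly_table, digits = 3, row.names = FALSE)
  invisible(x)
}
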