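# small fixed population used across the randomization tests
rand_fixture <- function(n_per_sex = 6, years = 2010:2011, seed = 14) {
  set.seed(seed)
  ids <- c(paste0("F", seq_len(n_per_sex)), paste0("M", seq_len(n_per_sex)))
  tab <- genotype_table(
    ids, rep(c("female", "male"), each = n_per_sex),
    rep(list(as.integer(years)), 2 * n_per_sex),
    sprintf("L%02d", 1:8),
    matrix(sample(101:106, 2 * n_per_sex * 8, TRUE), 2 * n_per_sex, 8),
    matrix(sample(101:106, 2 * n_per_sex * 8, TRUE), 2 * n_per_sex, 8))
  tab
}

test_that("unique_pairs keeps first observations in stable order", {
  tab <- rand_fixture()
  df <- data.frame(
    year = c(2010, 2011, 2012, 2010),
    female_id = c("F1", "F1", "F1", "F2"),
    male_id = c("M1", "M1", "M2", "M2"))
  pr <- pair_records(df, rand_fixture(years = 2010:2012))
  up <- unique_pairs(pr)
  expect_equal(nrow(up), 3L)
  expect_equal(up$year, c(2010L, 2010L, 2012L))
  expect_equal(up$female_id, c("F1", "F2", "F1"))
  # all-distinct input is returned unchanged (ordering aside)
  df2 <- data.frame(year = 2010, female_id = c("F1", "F2"),
                    male_id = c("M1", "M2"))
  pr2 <- pair_records(df2, tab)
  expect_equal(nrow(unique_pairs(pr2)), 2L)
})

test_that("observed_stats summarizes pair relatedness with fixed conventions", {
  tab <- rand_fixture(n_per_sex = 4, years = 2010L)
  pr <- pair_records(data.frame(year = 2010,
                                female_id = paste0("F", 1:4),
                                male_id = paste0("M", 1:4)), tab)
  rm <- pairwise_matrix(tab, "qg")
  # overwrite with chosen values through a synthetic estimator column
  rm$fix <- 0.2
  st <- observed_stats(pr, rm, "fix")
  expect_equal(st$mean_r, 0.2)
  expect_equal(st$median_r, 0.2)
  expect_equal(st$sd_r, 0)
  expect_equal(st$iqr_r, 0)
  expect_equal(st$count_gt_0125, 4L)
  expect_equal(st$count_gt_025, 0L)

  vals <- c(0.0, 0.1, 0.2, 0.3)
  rm$fix[match(kinmate:::dyad_key(pr$female_id, pr$male_id),
               attr(rm, "key"))] <- vals
  st <- observed_stats(pr, rm, "fix")
  expect_equal(st$median_r, 0.15)     # even-count midpoint
  expect_equal(st$iqr_r, 0.15)        # type-7 linear interpolation
  expect_equal(st$prop_gt_0125, 0.5)
  expect_equal(st$count_gt_025, 1L)

  # a pair whose dyad is absent from the matrix is a hard error
  rm2 <- rm[-match(kinmate:::dyad_key("F1", "M1"), attr(rm, "key")), ]
  attr(rm2, "key") <- kinmate:::dyad_key(rm2$id_a, rm2$id_b)
  expect_error(observed_stats(pr, rm2, "fix"), "F1-M1")
})

test_that("two-sided Monte-Carlo p follows the counting definitions", {
  # observed at the null median: both tails >= 0.5, capped at 1
  expect_equal(two_sided_p(0, c(-2, -1, 0, 1, 2)), 1)
  # observed below all B = 999 null values
  expect_equal(two_sided_p(-10, seq_len(999)), 2 / 1000)
  # constructed null 1..100, observed 3: 2 * (1 + 3) / 101
  expect_equal(two_sided_p(3, 1:100), 2 * 4 / 101)
  # extremity variant counts distance from the null center
  expect_equal(two_sided_p(3, 1:100, method = "extremity"),
               (1 + sum(abs(1:100 - 50.5) >= abs(3 - 50.5))) / 101)
  expect_error(two_sided_p(0, numeric(0)), "empty")
})

test_that("degenerate one-pair scope reproduces the observed pairing", {
  tab <- rand_fixture(n_per_sex = 1, years = 2010L)
  pr <- pair_records(data.frame(year = 2010, female_id = "F1",
                                male_id = "M1"), tab)
  rm <- pairwise_matrix(tab, "qg")
  rz <- randomize_pairings(pr, rm, "qg", B = 50, seed = 1)
  expect_true(all(rz$mean$null_values == rz$mean$observed))
  expect_equal(rz$mean$p_two_sided, 1)
  expect_equal(rz$median$p_two_sided, 1)
})

test_that("Monte-Carlo p matches exact enumeration on a one-year instance", {
  tab <- rand_fixture(n_per_sex = 3, years = 2010L, seed = 77)
  pr <- pair_records(data.frame(year = 2010,
                                female_id = paste0("F", 1:3),
                                male_id = paste0("M", 1:3)), tab)
  rm <- pairwise_matrix(tab, "qg")
  rz <- randomize_pairings(pr, rm, "qg", B = 10000, seed = 5)
  # exhaustive: all 3! = 6 male assignments
  P <- all_perms(3)
  rv <- outer(1:3, 1:3, function(i, j)
    r_lookup(rm, paste0("F", i), paste0("M", j), "qg"))
  nulls_mean <- apply(P, 1, function(pm) mean(rv[cbind(1:3, pm)]))
  nulls_med <- apply(P, 1, function(pm) median(rv[cbind(1:3, pm)]))
  expect_lt(abs(rz$mean$p_two_sided -
                  oracle_exact_p(rz$mean$observed, nulls_mean)), 0.02)
  expect_lt(abs(rz$median$p_two_sided -
                  oracle_exact_p(rz$median$observed, nulls_med)), 0.02)
})

test_that("replicates conserve ids and honor frozen remated pairs", {
  tab <- rand_fixture(n_per_sex = 5, years = 2010:2011)
  df <- data.frame(
    year = c(rep(2010, 4), rep(2011, 5)),
    female_id = c("F1", "F2", "F3", "F4", "F1", "F2", "F3", "F4", "F5"),
    male_id = c("M1", "M2", "M3", "M4", "M1", "M3", "M2", "M5", "M4"))
  pr <- pair_records(df, tab)
  expect_equal(sum(pr$remated), 1L)  # F1-M1 remates in 2011
  rm <- pairwise_matrix(tab, "qg")
  rz <- randomize_pairings(pr, rm, "qg", B = 40, seed = 3,
                           respect_remated = TRUE,
                           return_assignments = TRUE)
  asg <- attr(rz, "assignments")
  expect_length(asg, 40L)
  for (a in asg) {
    for (y in unique(pr$year)) {
      expect_setequal(a$female_id[a$year == y],
                      pr$female_id[pr$year == y])
      expect_setequal(a$male_id[a$year == y], pr$male_id[pr$year == y])
    }
    # the remated 2011 pair F1-M1 is frozen in every replicate
    expect_equal(a$male_id[a$year == 2011 & a$female_id == "F1"], "M1")
  }
})

test_that("full analysis returns coherent pooled and yearly results", {
  pop <- simulate_population(population_config(
    n_founders = 40L, n_years = 4L, pairs_per_year = c(8L, 14L),
    seed = 606))
  rep <- run_full_analysis(pop$table, pop$pairs, estimator = "qg",
                           b_pooled = 300, b_yearly = 200, seed = 11)
  expect_s3_class(rep, "random_mating_report")
  expect_equal(rep$n_unique_pairs, nrow(unique_pairs(pop$pairs)))
  expect_equal(nrow(rep$yearly_table), length(unique(pop$pairs$year)))
  expect_true(all(rep$yearly_table$p_mean > 0 &
                    rep$yearly_table$p_mean <= 1))
  expect_true(all(rep$yearly_table$p_median > 0 &
                    rep$yearly_table$p_median <= 1))
  expect_equal(rep$pooled$mean$B, 300L)
  expect_equal(rep$yearly[[1]]$median$B, 200L)
  expect_equal(rep$observed$n_pairs, rep$n_unique_pairs)
  # deterministic under the same seed
  rep2 <- run_full_analysis(pop$table, pop$pairs, estimator = "qg",
                            b_pooled = 300, b_yearly = 200, seed = 11)
  expect_identical(rep$pooled$median$p_two_sided,
                   rep2$pooled$median$p_two_sided)
  expect_identical(rep$yearly_table, rep2$yearly_table)
})
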