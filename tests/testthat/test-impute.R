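test_that("donor screening keeps correlated covariates and always the diagnosis", {
  set.seed(200)
  n <- 10000
  z <- rnorm(n)
  baseline <- data.frame(
    subject_id = as.character(seq_len(n)), group = "MCI",
    target = z + rnorm(n),                 # corr ~0.7 with z
    b_corr = z,                            # correlated donor
    a_noise = rnorm(n),                    # independent noise
    stringsAsFactors = FALSE)
  sel <- select_donor_variables(baseline, "target", threshold = 0.05)
  expect_true("b_corr" %in% sel)
  expect_false("a_noise" %in% sel)
  expect_true("group" %in% sel)
  # threshold 0 is a vacuous filter
  expect_setequal(select_donor_variables(baseline, "target", threshold = 0),
                  c("group", "b_corr", "a_noise"))
  baseline$target <- NA_real_
  expect_error(select_donor_variables(baseline, "target"), "no observed values")
})

test_that("imputing a complete cohort returns identical copies", {
  ch <- quick_cohort(n = 25, seed = 201)
  sets <- impute_chained(ch, impute_control(m = 4, n_iter = 2), seed = 1)
  expect_length(sets, 4)
  for (s in sets) expect_identical(s$baseline, ch$baseline)
})

test_that("PMM imputes observed donor values and never alters observed cells", {
  ch <- quick_cohort(n = 60, seed = 202)
  obs_abeta <- ch$baseline$abeta
  ch$baseline$abeta[c(3, 17)] <- NA
  sets <- impute_chained(ch, impute_control(m = 3, n_iter = 3, k_donors = 1),
                         seed = 5)
  for (s in sets) {
    filled <- s$baseline$abeta
    # PMM support property: imputations are observed values of the covariate
    expect_true(all(filled[c(3, 17)] %in% obs_abeta[-c(3, 17)]))
    # observed cells identical across all sets
    expect_identical(filled[-c(3, 17)], obs_abeta[-c(3, 17)])
  }
})

test_that("categorical covariates are imputed on their own levels", {
  ch <- quick_cohort(n = 120, seed = 203)
  ch$baseline$smoking[1:30] <- NA
  ch$baseline$bmi_cat[5:20] <- NA
  sets <- impute_chained(ch, impute_control(m = 2, n_iter = 2), seed = 6)
  expect_true(all(sets[[1]]$baseline$smoking %in% c("never", "former", "current")))
  expect_true(all(sets[[2]]$baseline$bmi_cat %in% c("<25", "25-30", ">30")))
})

test_that("a covariate with under 10 observed values is refused with advice", {
  ch <- quick_cohort(n = 30, seed = 204)
  ch$baseline$hippocampus[-(1:5)] <- NA
  expect_error(impute_chained(ch), "fewer than 10 observed.*exclude")
})

test_that("post-imputation pooled mean recovers the complete-data mean under MCAR", {
  cfg <- cohort_config("MCI", n_subjects = 500, missing_rates = c(none = 0),
                       seed = 205)
  ch <- simulate_cohort(cfg)
  full_mean <- mean(ch$baseline$abeta)
  set.seed(206)
  drop_idx <- which(runif(500) < 0.2)
  ch$baseline$abeta[drop_idx] <- NA
  sets <- impute_chained(ch, impute_control(m = 5, n_iter = 4), seed = 207)
  pooled <- mean(vapply(sets, function(s) mean(s$baseline$abeta), numeric(1)))
  mc_se <- sd(ch$baseline$abeta, na.rm = TRUE) / sqrt(length(drop_idx))
  expect_lt(abs(pooled - full_mean), 2.5 * mc_se)
})

test_that("Rubin pooling matches the hand-computed oracle", {
  res <- pool_rubin(c(1, 2, 3), c(0.1, 0.1, 0.1))
  expect_equal(unname(res$estimate), 2.0)
  expect_equal(unname(res$variance), 0.1 + (1 + 1 / 3) * 1.0, tolerance = 1e-12)

  # m = 1: the single estimate, no between-variance
  one <- pool_rubin(5, 0.3)
  expect_equal(unname(one$estimate), 5)
  expect_equal(unname(one$variance), 0.3)

  # identical estimates: total variance equals within-variance
  same <- pool_rubin(c(2, 2, 2), c(0.2, 0.2, 0.2))
  expect_equal(unname(same$variance), 0.2)
  expect_identical(unname(same$df), Inf)

  # permutation invariance in set order
  a <- pool_rubin(c(1, 2, 3), c(0.1, 0.2, 0.3))
  b <- pool_rubin(c(3, 1, 2), c(0.3, 0.1, 0.2))
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$variance, b$variance)

  em <- matrix(1:6, 2, dimnames = list(NULL, c("a", "b", "c")))
  vm <- matrix(1, 2, 3, dimnames = list(NULL, c("a", "b", "x")))
  expect_error(pool_rubin(em, vm), "names differ")
})

test_that("pooled 95% intervals attain nominal coverage under MCAR", {
  # known-mean toy: y correlated with an always-observed x; 30% MCAR in y
  reps <- 200
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(3000 + r)
    n <- 80
    x <- rnorm(n)
    y <- 1.5 * x + rnorm(n)
    visits <- data.frame(subject_id = as.character(1:n), time_years = 0,
                         outcome = 25)
    baseline <- data.frame(subject_id = as.character(1:n), group = "MCI",
                           x = x, y = y, stringsAsFactors = FALSE)
    baseline$y[runif(n) < 0.3] <- NA
    ch <- long_cohort(visits, baseline)
    sets <- impute_chained(ch, impute_control(m = 3, n_iter = 2),
                           seed = 9000 + r)
    ests <- vapply(sets, function(s) mean(s$baseline$y), numeric(1))
    vars <- vapply(sets, function(s) var(s$baseline$y) / n, numeric(1))
    p <- pool_rubin(ests, vars, dfcom = n - 1)
    ci <- p$estimate + c(-1, 1) * qt(0.975, p$df) * p$se
    covered[r] <- ci[1] <= 0 && 0 >= ci[1] && 0 <= ci[2]
  }
  # binomial error around 0.95 at 200 replications
  expect_gt(mean(covered), 0.885)
  expect_lte(mean(covered), 1)
})
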