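test_that("baseline covariates match their configured distributions", {
  set.seed(100)
  cfg <- cohort_config("MCI", n_subjects = 5000)
  bl <- generate_baseline(cfg)
  # Monte-Carlo error at n=5000 plus the small clip/round perturbation
  expect_equal(mean(bl$mmse_bl), 26.5, tolerance = 0.15 / 26.5)
  expect_lt(abs(sd(bl$mmse_bl) - 2.3), 0.15)
  expect_lt(abs(mean(bl$age) - 66), 0.35)
  # APOE e4 dose frequencies within binomial error
  freq <- as.numeric(table(factor(bl$apoe4, levels = c(0, 1, 2)))) / 5000
  expect_true(all(abs(freq - c(0.224, 0.468, 0.308)) < 0.03))
  # pTau is log-normal with the configured median
  expect_lt(abs(median(bl$ptau) - 29.7), 1.2)
  expect_true(all(bl$mmse_bl >= 0 & bl$mmse_bl <= 30))
})

test_that("degenerate distributions give every subject the configured mean", {
  set.seed(101)
  cfg <- cohort_config("MCI", n_subjects = 3,
                       covariate_params = point_mass_params("MCI"))
  bl <- generate_baseline(cfg)
  expect_equal(bl$age, rep(66, 3))
  expect_equal(bl$mmse_bl, rep(round(26.5), 3))
  expect_equal(bl$sex, rep("female", 3))
  expect_equal(bl$apoe4, rep(0, 3))
  expect_equal(bl$ptau, rep(29.7, 3), tolerance = 1e-12)
})

test_that("invalid distribution parameters name the covariate", {
  p <- covariate_defaults("MCI")
  p$abeta$sd <- -1
  expect_error(cohort_config("MCI", covariate_params = p), "abeta")
})

test_that("noiseless trajectories equal the rounded, clipped fixed curve", {
  cfg <- cohort_config("MCI", n_subjects = 15, re_sd_intercept = 0,
                       re_sd_slope = 0, re_corr = 0, resid_sd = 0,
                       visit_jitter = 0, dropout_hazard_per_year = 0,
                       missing_rates = c(none = 0), seed = 21)
  ch <- simulate_cohort(cfg)
  # every subject has exactly 6 visits on the annual schedule
  expect_true(all(table(ch$visits$subject_id) == 6))
  pred <- predict_cohort(cfg$true_coefficients, ch)
  expect_identical(ch$visits$outcome,
                   pmin(pmax(round(pred), 0), 30))
})

test_that("a Figure-2-style subject reproduces the derived 5-year value", {
  # fixed prediction at t=5 for the median MCI patient is 21.5101 (hand
  # dot-product over the reference table); noiseless simulated outcome is
  # its rounded value
  baseline <- data.frame(subject_id = "p1", group = "MCI", age = 66,
                         sex = "male", mmse_bl = 27, abeta = 796.22,
                         ptau = exp(3.415), stringsAsFactors = FALSE)
  cfg <- cohort_config("MCI", n_subjects = 1, re_sd_intercept = 0,
                       re_sd_slope = 0, re_corr = 0, resid_sd = 0,
                       visit_jitter = 0, dropout_hazard_per_year = 0, seed = 1)
  ch <- generate_trajectories(baseline, cfg)
  y5 <- ch$visits$outcome[ch$visits$time_years == 5]
  expect_identical(y5, round(21.510127))
})

test_that("generation is deterministic in the seed and honors bounds", {
  cfg <- cohort_config("dementia", n_subjects = 40, resid_sd = 8, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$visits, b$visits)
  expect_identical(a$baseline, b$baseline)
  expect_true(all(a$visits$outcome >= 0 & a$visits$outcome <= 30))
  c2 <- simulate_cohort(cohort_config("dementia", n_subjects = 40,
                                      resid_sd = 8, seed = 78))
  expect_false(identical(a$visits, c2$visits))
})

test_that("a generating model referencing an absent covariate is a schema error", {
  cfg <- cohort_config("MCI", n_subjects = 3, seed = 1)
  bl <- generate_baseline(cfg)
  bl$abeta <- NULL
  expect_error(generate_trajectories(bl, cfg), "absent from baseline.*abeta")
})

test_that("missingness masking matches the configured rates", {
  cfg0 <- cohort_config("MCI", n_subjects = 50, seed = 31,
                        missing_rates = c(abeta = 0, tbv = 0))
  ch <- simulate_cohort(cfg0)
  expect_false(anyNA(ch$baseline$abeta))

  set.seed(32)
  cfg <- cohort_config("MCI", n_subjects = 5000, seed = 32)
  bl <- generate_baseline(cfg)
  ch_full <- generate_trajectories(bl, cfg)
  ch_miss <- apply_missingness(ch_full, cfg)
  expect_lt(abs(mean(is.na(ch_miss$baseline$tbv)) - 0.26), 0.03)
  # protected columns never masked
  expect_false(anyNA(ch_miss$baseline$age))
  expect_false(anyNA(ch_miss$baseline$mmse_bl))

  cfg1 <- cohort_config("MCI", n_subjects = 30, seed = 33,
                        missing_rates = c(gds = 1.0))
  ch1 <- simulate_cohort(cfg1)
  expect_true(all(is.na(ch1$baseline$gds)))
  expect_false(anyNA(ch1$baseline$sbp))
})

test_that("per-subject OLS intercept/slope covariance recovers the RE covariance", {
  # balanced design: empirical covariance of OLS estimates should match
  # G + sigma^2 (X'X)^{-1} (closed form for a shared design)
  cfg <- cohort_config("MCI", n_subjects = 2000, re_sd_intercept = 2,
                       re_sd_slope = 1, re_corr = -0.3, resid_sd = 1.5,
                       visit_jitter = 0, dropout_hazard_per_year = 0,
                       integer_outcome = FALSE, missing_rates = c(none = 0),
                       seed = 55)
  ch <- simulate_cohort(cfg)
  pred <- predict_cohort(cfg$true_coefficients, ch)
  dev <- ch$visits$outcome - pmin(pmax(pred, 0), 30)
  tt <- ch$visits$time_years
  est <- t(vapply(split(seq_along(dev), ch$visits$subject_id), function(ix) {
    coef(lm(dev[ix] ~ tt[ix]))
  }, numeric(2)))
  X <- cbind(1, 0:5)
  expected <- matrix(c(4, -0.6, -0.6, 1), 2, 2) + 1.5^2 * solve(crossprod(X))
  emp <- cov(est)
  expect_lt(max(abs(emp - expected)) / max(abs(expected)), 0.12)
})
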