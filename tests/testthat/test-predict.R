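# The printed worked examples are reproduced within the budget that
# 4-decimal coefficient rounding allows: +/- 0.5 years on prognosis times,
# +/- 0.6 points on predicted scores.

test_that("the MCI prognosis worked examples are reproduced", {
  tab <- reference_coefs("MCI")
  pt <- fig3_mci_patient()
  t_nat <- time_to_threshold(tab, pt, threshold = 20)
  expect_lt(abs(t_nat - 6.0), 0.5)
  t_trt <- time_to_threshold(tab, pt, threshold = 20,
                             treatment = treatment_spec(0.3))
  expect_lt(abs(t_trt - 8.6), 0.5)
  expect_equal(t_trt, t_nat / 0.7, tolerance = 1e-3)
})

test_that("the dementia prognosis worked examples are reproduced", {
  tab <- reference_coefs("dementia")
  pt <- fig3_dementia_patient()
  t_nat <- time_to_threshold(tab, pt, threshold = 15)
  expect_lt(abs(t_nat - 2.3), 0.5)
  t_trt <- time_to_threshold(tab, pt, threshold = 15,
                             treatment = treatment_spec(0.3))
  expect_lt(abs(t_trt - 3.3), 0.5)
})

test_that("the 5-year MCI predictions match the printed values", {
  tab <- reference_coefs("MCI")
  pt <- fig2_mci_patient()
  nat5 <- predict_mean(tab, pt, times = 5)$pred
  expect_lt(abs(nat5 - 21.0), 0.6)
  f <- function(t) predict_mean(tab, pt, times = t)$pred
  trt5 <- apply_treatment(f, treatment_spec(0.3))(5)
  expect_lt(abs(trt5 - 23.7), 0.6)
  # time dilation evaluates the natural curve at (1 - r) t
  expect_equal(trt5, f(3.5), tolerance = 1e-10)
})

test_that("time dilation scales every crossing time by exactly 1/(1 - r)", {
  tab <- reference_coefs("MCI")
  pt <- fig3_mci_patient()
  base <- time_to_threshold(tab, pt, 20)
  for (r in c(0, 0.1, 0.3, 0.5)) {
    tr <- time_to_threshold(tab, pt, 20, treatment_spec(r), horizon = 25)
    expect_lt(abs(tr * (1 - r) - base), 1e-3)
  }
})

test_that("crossing times round-trip through the trajectory", {
  tab <- reference_coefs("dementia")
  pt <- fig3_dementia_patient()
  t15 <- time_to_threshold(tab, pt, 15)
  expect_lt(abs(predict_mean(tab, pt, times = t15)$pred - 15), 1e-3)
})

test_that("treatment edge cases behave algebraically", {
  f <- function(t) 28 - 2 * t        # linear decline
  expect_equal(apply_treatment(f, treatment_spec(0))(3.7), f(3.7))
  g_dil <- apply_treatment(f, treatment_spec(0.4, "time_dilation"))
  g_scl <- apply_treatment(f, treatment_spec(0.4, "decline_scaling"))
  # for linear trajectories both mechanisms coincide
  expect_equal(g_dil(4), g_scl(4), tolerance = 1e-12)
  # treated time-to-threshold is untreated/(1 - r) under both
  expect_equal(uniroot(function(t) g_scl(t) - 20, c(0, 20))$root,
               4 / 0.6, tolerance = 1e-6)
  expect_error(treatment_spec(1), "reduction")
})

test_that("a threshold already exceeded at baseline is an error, not-reached is NA", {
  tab <- reference_coefs("MCI")
  pt <- fig3_mci_patient()
  expect_error(time_to_threshold(tab, pt, threshold = 29),
               "exceeded at baseline")
  nr <- time_to_threshold(tab, pt, threshold = 20, horizon = 2)
  expect_true(is.na(nr))
  expect_false(attr(nr, "reached"))
})

test_that("uncertainty bands degenerate correctly and centre on the mean", {
  tab <- reference_coefs("MCI")
  pt <- fig2_mci_patient()
  band0 <- simulate_individual_band(tab, pt, re_cov = matrix(0, 2, 2),
                                    times = c(0, 2, 5), n = 100, seed = 1)
  for (j in 1:3)
    expect_true(all(abs(as.numeric(band0$band[j, -1]) - band0$mean[j]) < 1e-9))
  expect_error(simulate_individual_band(tab, pt, matrix(0, 2, 2), n = 1),
               "at least 2")
  # slower decline ranks at the top of a degenerate band
  expect_equal(percentile_of(band0, 5, band0$mean[3] + 1), 100)

  G <- matrix(c(4, -0.6, -0.6, 1), 2, 2)
  band <- simulate_individual_band(tab, pt, G, times = c(0, 5), n = 4000,
                                   seed = 2)
  # symmetric random effects: the mean trajectory sits near the median
  expect_lt(abs(percentile_of(band, 5, band$mean[2]) - 50), 3)
})

test_that("the treated 5-year value ranks near the 69th percentile of natural variation", {
  # with the default heterogeneity (intercept SD 2, slope SD 1, corr -0.3)
  # the SD of the random offset at 5 years is sqrt(4 + 25 - 6) = 4.8
  tab <- reference_coefs("MCI")
  pt <- fig2_mci_patient()
  G <- matrix(c(4, -0.6, -0.6, 1), 2, 2)
  band <- simulate_individual_band(tab, pt, G, times = c(0, 5), n = 4000,
                                   seed = 3)
  q <- quantile(band$draws[, 2], c(0.05, 0.95))
  expect_lt(abs(q[[1]] - 13.6), 1.5)   # 21.51 - 1.645 * 4.8
  expect_lt(abs(q[[2]] - 29.4), 1.5)
  f <- function(t) predict_mean(tab, pt, times = t)$pred
  treated5 <- apply_treatment(f, treatment_spec(0.3))(5)
  expect_lt(abs(percentile_of(band, 5, treated5) - 69), 5)
})

test_that("population fans are monotone in percentile and respect bounds", {
  ch <- quick_cohort(n = 60, seed = 620)
  fit <- fit_lmm(build_design(ch, tier_terms("base")))
  fan <- population_fan(fit, cohort = ch, times = seq(0.5, 5, 0.5))
  pc <- grep("^p[0-9]", names(fan), value = TRUE)
  for (i in seq_len(nrow(fan))) {
    v <- as.numeric(fan[i, pc])
    expect_true(all(diff(v) >= -1e-9))
    expect_true(all(v >= 0 & v <= 30))
  }
  # slope heterogeneity widens the fan over time
  gap <- fan$p84 - fan$p16
  expect_gt(gap[nrow(fan)], gap[1])
})

test_that("identical noiseless subjects give a collapsed fan", {
  cfg <- cohort_config("MCI", n_subjects = 12, re_sd_intercept = 0,
                       re_sd_slope = 0, re_corr = 0, resid_sd = 0,
                       integer_outcome = FALSE, visit_jitter = 0,
                       dropout_hazard_per_year = 0,
                       covariate_params = point_mass_params("MCI"),
                       missing_rates = c(none = 0), seed = 621)
  ch <- simulate_cohort(cfg)
  fit <- fit_lmm(build_design(ch, tier_terms("base")))
  fan <- population_fan(fit, cohort = ch, times = c(1, 3))
  pc <- grep("^p[0-9]", names(fan), value = TRUE)
  spread <- apply(as.matrix(fan[, pc]), 1, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-6)
})
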