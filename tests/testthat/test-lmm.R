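test_that("design centering makes time columns vanish at t = time_center", {
  ch <- quick_cohort(n = 8, seed = 300, visit_jitter = 0)
  # force one visit exactly at the centering constant
  ch$visits$time_years[ch$visits$time_years == 1] <- 2.3
  ch <- long_cohort(ch$visits, ch$baseline)
  des <- build_design(ch, tier_terms("biomarker"), time_center = 2.3)
  at_c <- abs(des$time - 2.3) < 1e-9
  expect_true(any(at_c))
  expect_true(all(abs(des$X[at_c, c("time_c", "time_c2", "time_c3")]) < 1e-12))
  expect_true(all(abs(des$X[at_c, grep(":time_c", colnames(des$X))]) < 1e-12))
})

test_that("the dementia reference prediction at t = 2.3 is the covariate constant part", {
  tab <- reference_coefs("dementia")
  pred <- predict_mean(tab, fig3_dementia_patient(), times = 2.3)$pred
  # hand dot-product over the table: -10.2450 + 0.1020*66 + 1.0006*20 +
  # 0.5419*2 - 1.0403*3.498 + 0.0019*625 = 15.1313
  expect_equal(pred, 15.13133, tolerance = 1e-6)
})

test_that("design construction is invariant to row order", {
  ch <- quick_cohort(n = 12, seed = 301)
  des1 <- build_design(ch, tier_terms("base"))
  perm <- sample(nrow(ch$visits))
  ch2 <- long_cohort(ch$visits[perm, ], ch$baseline)
  des2 <- build_design(ch2, tier_terms("base"))
  expect_equal(des1$X, des2$X)
  expect_equal(des1$y, des2$y)
})

test_that("with zero random-effect variance REML collapses to OLS", {
  cfg <- cohort_config("MCI", n_subjects = 250, re_sd_intercept = 0,
                       re_sd_slope = 0, re_corr = 0, resid_sd = 1.5,
                       integer_outcome = FALSE, missing_rates = c(none = 0),
                       seed = 302)
  ch <- simulate_cohort(cfg)
  des <- build_design(ch, true_mci_terms())
  fit <- fit_lmm(des)
  # estimated heterogeneity collapses toward zero (half-normal sampling
  # noise of the boundary estimate allowed for)
  expect_lt(sqrt(fit$re_cov[1, 1]), 0.6)
  expect_lt(sqrt(fit$re_cov[2, 2]), 0.35)
  ols <- qr.solve(des$X, des$y)
  expect_lt(max(abs(fit$coefficients$estimate - ols)), 0.1)
})

test_that("refitting the same data reproduces the coefficients", {
  ch <- quick_cohort(n = 50, seed = 303)
  des <- build_design(ch, tier_terms("base"))
  f1 <- fit_lmm(des)
  f2 <- fit_lmm(des)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
})

test_that("variance components are recovered at moderate n", {
  cfg <- cohort_config("MCI", n_subjects = 400, re_sd_intercept = 2,
                       re_sd_slope = 1, re_corr = -0.3, resid_sd = 1.5,
                       integer_outcome = FALSE, visit_jitter = 0,
                       dropout_hazard_per_year = 0,
                       missing_rates = c(none = 0), seed = 304)
  ch <- simulate_cohort(cfg)
  fit <- fit_lmm(build_design(ch, true_mci_terms()))
  expect_lt(abs(sqrt(fit$re_cov[1, 1]) - 2), 0.35)
  expect_lt(abs(sqrt(fit$re_cov[2, 2]) - 1), 0.2)
  expect_lt(abs(sqrt(fit$resid_var) - 1.5), 0.15)
})

test_that("closed-form empirical-Bayes BLUPs agree with the mixed-model solver", {
  ch <- quick_cohort(n = 40, seed = 305)
  fit <- fit_lmm(build_design(ch, tier_terms("base")))
  ours <- estimate_blups(fit)
  lme4_modes <- lme4::ranef(fit$merMod)$.subj
  ids <- rownames(lme4_modes)
  j <- match(ids, ours$subject_id)
  expect_lt(max(abs(ours$b0[j] - lme4_modes[, 1])), 1e-8)
  expect_lt(max(abs(ours$b1[j] - lme4_modes[, 2])), 1e-8)
})

test_that("BLUPs vanish for error-free subjects and shrink single observations", {
  # subjects observed exactly on the fixed curve carry zero random effects
  cfg <- cohort_config("MCI", n_subjects = 10, re_sd_intercept = 0,
                       re_sd_slope = 0, re_corr = 0, resid_sd = 0,
                       integer_outcome = FALSE, visit_jitter = 0,
                       dropout_hazard_per_year = 0,
                       missing_rates = c(none = 0), seed = 306)
  ch <- simulate_cohort(cfg)
  fit0 <- fit_lmm(build_design(ch, true_mci_terms()))
  # impose non-degenerate variance components, keep the exact fixed effects
  fit0$re_cov <- matrix(c(4, -0.6, -0.6, 1), 2, 2)
  fit0$resid_var <- 2
  fit0$coefficients$estimate <- reference_coefs("MCI")$estimate[
    match(fit0$coefficients$term, reference_coefs("MCI")$term)]
  b <- estimate_blups(fit0)
  expect_lt(max(abs(c(b$b0, b$b1))), 1e-8)

  # one-visit subject: the BLUP is strictly shrunk toward zero
  ch1 <- quick_cohort(n = 30, seed = 307)
  keep <- ch1$visits$time_years == 0 | ch1$visits$subject_id != "S0001"
  ch1 <- long_cohort(ch1$visits[keep, ], ch1$baseline)
  fit1 <- fit_lmm(build_design(ch1, tier_terms("base")))
  b1 <- estimate_blups(fit1)
  des1 <- fit1$design
  sel <- des1$subject_id == "S0001"
  raw_resid <- des1$y[sel] - drop(des1$X[sel, ] %*% fit1$coefficients$estimate)
  expect_lt(abs(b1$b0[b1$subject_id == "S0001"]), abs(raw_resid) + 1e-12)
})

test_that("BLUP slopes track true slopes better with more visits", {
  cors <- vapply(c(2, 4, 7), function(fu) {
    cfg <- cohort_config("MCI", n_subjects = 150, max_followup_years = fu,
                         dropout_hazard_per_year = 0, visit_jitter = 0,
                         missing_rates = c(none = 0), seed = 310 + fu)
    ch <- simulate_cohort(cfg)
    fit <- fit_lmm(build_design(ch, true_mci_terms()))
    b <- estimate_blups(fit)
    truth <- attr(ch, "random_effects")
    cor(b$b1, truth$b1[match(b$subject_id, truth$subject_id)])
  }, numeric(1))
  expect_true(all(cors > 0))
  expect_true(all(diff(cors) > 0))
})

test_that("Wald p-values of a null coefficient are uniform", {
  pvals <- vapply(seq_len(250), function(r) {
    cfg <- cohort_config("MCI", n_subjects = 70, max_followup_years = 3,
                         dropout_hazard_per_year = 0,
                         missing_rates = c(none = 0), seed = 5000 + r)
    ch <- simulate_cohort(cfg)
    # tbv has no effect in the generating model
    terms <- rbind(true_mci_terms(),
                   data.frame(term = "tbv", covariate = "tbv",
                              transform = "identity", role = "main"))
    fit <- fit_lmm(build_design(ch, terms))
    fit$coefficients$p[fit$coefficients$term == "tbv"]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
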