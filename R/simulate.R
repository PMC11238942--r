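#' Baseline covariate distributions per diagnosis group
#'
#' Default generating distributions for the baseline covariates, matching
#' the published baseline characteristics of the amyloid-positive memory
#' clinic cohort the reference models were built in (means/SDs for
#' continuous covariates, category probabilities for discrete ones).
#' Continuous covariates are normal except CSF pTau, which is log-normal
#' (matching the model's log transform); values are truncated to plausible
#' instrument ranges.
#'
#' @param group `"MCI"` or `"dementia"`.
#' @param outcome `"mmse"` or `"ravlt"`; with `"ravlt"` a baseline RAVLT
#'   score (`ravlt_bl`) is generated in addition.
#' @return named list of per-covariate distribution specs.
#' @export
covariate_defaults <- function(group = c("MCI", "dementia"),
                               outcome = c("mmse", "ravlt")) {
  group <- match.arg(group)
  outcome <- match.arg(outcome)
  norm <- function(mean, sd, min = -Inf, max = Inf, integer = FALSE)
    list(dist = "normal", mean = mean, sd = sd, min = min, max = max, integer = integer)
  cat_ <- function(levels, probs)
    list(dist = "categorical", levels = levels, probs = probs / sum(probs))
  lnorm <- function(meanlog, sdlog)
    list(dist = "lognormal", meanlog = meanlog, sdlog = sdlog)
  if (group == "MCI") {
    p <- list(
      age = norm(66, 7, 40, 95),
      sex = cat_(c("female", "male"), c(0.455, 0.545)),
      mmse_bl = norm(26.5, 2.3, 0, 30, integer = TRUE),
      apoe4 = cat_(c(0, 1, 2), c(0.224, 0.468, 0.308)),
      abeta = norm(789, 217, 150, 1800),
      # median 29.7, IQR 22.9-41.0 pg/mL
      ptau = lnorm(log(29.7), (log(41.0) - log(22.9)) / (2 * stats::qnorm(0.75))),
      tbv = norm(1102, 113, 700, 1600),
      hippocampus = norm(7.0, 0.9, 3, 11),
      education_years = norm(12.5, 3.1, 6, 20),
      gds = norm(3.0, 2.5, 0, 15),
      sbp = norm(146, 19, 80, 220),
      dbp = norm(84, 10, 40, 130),
      bmi_cat = cat_(c("<25", "25-30", ">30"), c(0.542, 0.400, 0.058)),
      smoking = cat_(c("never", "former", "current"), c(0.476, 0.352, 0.173)))
    if (outcome == "ravlt") p$ravlt_bl <- norm(30.2, 7.3, 0, 75, integer = TRUE)
  } else {
    p <- list(
      age = norm(65, 7, 40, 95),
      sex = cat_(c("female", "male"), c(0.492, 0.508)),
      mmse_bl = norm(22.3, 3.8, 0, 30, integer = TRUE),
      apoe4 = cat_(c(0, 1, 2), c(0.283, 0.483, 0.234)),
      abeta = norm(742, 205, 150, 1800),
      ptau = lnorm(log(33.5), (log(45.3) - log(24.3)) / (2 * stats::qnorm(0.75))),
      tbv = norm(1066, 106, 700, 1600),
      hippocampus = norm(6.6, 0.9, 3, 11),
      education_years = norm(12.0, 2.9, 6, 20),
      gds = norm(2.7, 2.3, 0, 15),
      sbp = norm(148, 19, 80, 220),
      dbp = norm(84, 10, 40, 130),
      bmi_cat = cat_(c("<25", "25-30", ">30"), c(0.622, 0.303, 0.075)),
      smoking = cat_(c("never", "former", "current"), c(0.508, 0.346, 0.146)))
    if (outcome == "ravlt") p$ravlt_bl <- norm(22.9, 8.1, 0, 75, integer = TRUE)
  }
  p
}

#' Default baseline missingness rates
#'
#' Per-covariate probability that a baseline value is missing, emulating
#' the availability pattern in the development cohort: CSF biomarkers
#' available in ~91% of participants, volumetric MRI in ~74%, modest
#' missingness elsewhere.  Age, sex, baseline MMSE and diagnosis are always
#' complete.
#' @export
default_missing_rates <- function() {
  c(abeta = 0.09, ptau = 0.09, tbv = 0.26, hippocampus = 0.26, apoe4 = 0.03,
    education_years = 0.05, gds = 0.05, sbp = 0.05, dbp = 0.05,
    bmi_cat = 0.05, smoking = 0.05)
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the simulator emulates: the baseline
#' covariate distributions, the true fixed-effect trajectory (a
#' [coef_table()], by default the group's reference model), the
#' random-intercept/slope distribution, residual noise, the annual visit
#' schedule with dropout, and baseline covariate missingness.
#'
#' The reference models do not report random-effect or residual SDs, so the
#' defaults here (intercept SD 2 points, slope SD 1 point/year, correlation
#' -0.3, residual SD 1.5 points) are the package's own realistic choice,
#' calibrated so total outcome variation is comparable to the development
#' cohort; they are configurable and not claimed to match the study.
#'
#' @param group `"MCI"` or `"dementia"`.
#' @param n_subjects number of subjects (defaults: 310 MCI, 651 dementia,
#'   the development-cohort sizes).
#' @param outcome `"mmse"` or `"ravlt"`.
#' @param visit_interval_years scheduled spacing of visits.
#' @param max_followup_years last scheduled visit time.
#' @param dropout_hazard_per_year rate of the per-visit geometric dropout;
#'   the probability of continuing past each scheduled follow-up visit is
#'   `exp(-hazard * interval)`.  Defaults (0.15 MCI, 0.25 dementia) are
#'   calibrated to the development cohort's mean measurement counts
#'   (4.2 and 3.2).
#' @param dropout_mode `"mcar"` (default) or `"outcome"`, where subjects
#'   with lower current outcome scores drop out faster.
#' @param covariate_params per-covariate distribution specs, see
#'   [covariate_defaults()].
#' @param true_coefficients [coef_table()] used as the generating fixed
#'   effects.
#' @param re_sd_intercept,re_sd_slope,re_corr random-effect SDs (outcome
#'   points, points/year) and correlation.
#' @param resid_sd residual SD (outcome points).
#' @param missing_rates named per-covariate missingness probabilities.
#' @param visit_jitter half-width (years) of the uniform jitter on
#'   follow-up visit times (0 disables); avoids perfectly collinear
#'   designs.
#' @param integer_outcome round generated outcomes to integers (default
#'   TRUE, as the instruments are integer-valued); disable for exact
#'   degenerate-limit checks.
#' @param seed integer seed; `simulate_cohort()` sets it once up front.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(group = c("MCI", "dementia"),
                          n_subjects = NULL,
                          outcome = c("mmse", "ravlt"),
                          visit_interval_years = 1.0,
                          max_followup_years = 5.0,
                          dropout_hazard_per_year = NULL,
                          dropout_mode = c("mcar", "outcome"),
                          covariate_params = NULL,
                          true_coefficients = NULL,
                          re_sd_intercept = 2.0,
                          re_sd_slope = 1.0,
                          re_corr = -0.3,
                          resid_sd = 1.5,
                          missing_rates = default_missing_rates(),
                          visit_jitter = 0.1,
                          integer_outcome = TRUE,
                          seed = NULL) {
  group <- match.arg(group)
  outcome <- match.arg(outcome)
  dropout_mode <- match.arg(dropout_mode)
  n_subjects <- n_subjects %||% if (group == "MCI") 310L else 651L
  # per-visit retention calibrated to ~4.2 (MCI) / ~3.2 (dementia) visits
  dropout_hazard_per_year <- dropout_hazard_per_year %||%
    if (group == "MCI") 0.15 else 0.25
  if (n_subjects < 1) stop_ct("n_subjects must be >= 1")
  if (visit_interval_years <= 0 || max_followup_years <= 0)
    stop_ct("visit interval and max follow-up must be positive")
  if (re_sd_intercept < 0 || re_sd_slope < 0 || resid_sd < 0)
    stop_ct("SDs must be non-negative")
  if (abs(re_corr) > 1) stop_ct("re_corr must be in [-1, 1]")
  if (dropout_hazard_per_year < 0) stop_ct("dropout hazard must be >= 0")
  if (any(missing_rates < 0 | missing_rates > 1))
    stop_ct("missing rates must be probabilities")
  if (visit_jitter < 0 || visit_jitter >= visit_interval_years / 2)
    stop_ct("visit_jitter must be in [0, interval/2)")
  covariate_params <- covariate_params %||% covariate_defaults(group, outcome)
  for (nm in names(covariate_params)) {
    sp <- covariate_params[[nm]]
    ok <- switch(sp$dist,
                 normal = is_scalar_num(sp$mean) && is_scalar_num(sp$sd) && sp$sd >= 0,
                 lognormal = is_scalar_num(sp$meanlog) && is_scalar_num(sp$sdlog) && sp$sdlog >= 0,
                 categorical = length(sp$levels) == length(sp$probs) &&
                   all(sp$probs >= 0) && sum(sp$probs) > 0,
                 FALSE)
    if (!isTRUE(ok))
      stop_ct("invalid distribution parameters for covariate '", nm, "'")
  }
  true_coefficients <- true_coefficients %||%
    (if (outcome == "mmse") reference_coefs(group) else synthetic_ravlt_coefs(group))
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 outcome = outcome,
                 visit_interval_years = visit_interval_years,
                 max_followup_years = max_followup_years,
                 dropout_hazard_per_year = dropout_hazard_per_year,
                 dropout_mode = dropout_mode,
                 covariate_params = covariate_params,
                 true_coefficients = true_coefficients,
                 re_sd_intercept = re_sd_intercept, re_sd_slope = re_sd_slope,
                 re_corr = re_corr, resid_sd = resid_sd,
                 missing_rates = missing_rates, visit_jitter = visit_jitter,
                 integer_outcome = isTRUE(integer_outcome),
                 seed = seed),
            class = "cohort_config")
}

#' Synthetic generating model for the RAVLT outcome
#'
#' No reference coefficient table exists for RAVLT Immediate Recall, so the
#' simulator uses a synthetic one: the group's MMSE table with the time
#' curve and interactions rescaled to the 0-75 instrument range and the
#' baseline-MMSE term replaced by a baseline-RAVLT term.  It exists to
#' exercise the pipeline on the alternative bounded outcome, not to mirror
#' any estimated model.
#'
#' @param group `"MCI"` or `"dementia"`.
#' @return a [coef_table()] with outcome `"ravlt"`.
#' @export
synthetic_ravlt_coefs <- function(group = c("MCI", "dementia")) {
  group <- match.arg(group)
  tab <- reference_coefs(group)
  df <- as.data.frame(tab)
  scale <- 75 / 30
  df$estimate[df$role %in% c("intercept", "time", "interaction")] <-
    df$estimate[df$role %in% c("intercept", "time", "interaction")] * scale
  bl <- df$covariate == "mmse_bl" & !is.na(df$covariate)
  df$term[bl] <- sub("mmse_bl", "ravlt_bl", df$term[bl])
  df$covariate[bl] <- "ravlt_bl"
  df$se <- NA_real_
  coef_table(df, group = group, outcome = "ravlt",
             bounds = outcome_bounds("ravlt"),
             time_center = attr(tab, "time_center"))
}

#' Generate a baseline covariate table
#'
#' One row per subject; continuous covariates drawn from their configured
#' normal/log-normal distributions and truncated to plausible ranges,
#' categorical covariates from their configured probabilities.  Called with
#' the global RNG; [simulate_cohort()] seeds it once.
#'
#' @param config a [cohort_config()].
#' @return data frame (`subject_id`, `group`, covariates), complete.
#' @export
generate_baseline <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    group = config$group, stringsAsFactors = FALSE)
  for (nm in names(config$covariate_params)) {
    sp <- config$covariate_params[[nm]]
    x <- switch(sp$dist,
      normal = {
        v <- stats::rnorm(n, sp$mean, sp$sd)
        v <- clip(v, c(sp$min, sp$max))
        if (isTRUE(sp$integer)) round(v) else v
      },
      lognormal = stats::rlnorm(n, sp$meanlog, sp$sdlog),
      categorical = {
        lev <- sp$levels
        idx <- sample.int(length(lev), n, replace = TRUE, prob = sp$probs)
        if (is.numeric(lev)) lev[idx] else as.character(lev[idx])
      })
    out[[nm]] <- x
  }
  out
}

#' Generate outcome trajectories around the true fixed-effect curve
#'
#' For each subject a random intercept/slope pair is drawn from the
#' configured bivariate normal; the outcome at visit time `t` is the
#' fixed-effect prediction from `true_coefficients` at the subject's
#' covariates, plus `b0 + b1 * t` (raw time) and residual noise, rounded to
#' an integer and clipped to the instrument bounds.  Visits follow the
#' schedule (with optional jitter after baseline) until geometric dropout
#' or the maximum follow-up.
#'
#' @param baseline complete baseline table from [generate_baseline()].
#' @param config a [cohort_config()].
#' @return a [long_cohort()]; the drawn random effects are attached as
#'   attribute `"random_effects"`.
#' @export
generate_trajectories <- function(baseline, config) {
  stopifnot(inherits(config, "cohort_config"))
  tab <- config$true_coefficients
  need <- unique(stats::na.omit(tab$covariate))
  have <- c(names(baseline), "sex")
  gap <- setdiff(need, have)
  if (length(gap))
    stop_ct("true_coefficients reference covariates absent from baseline: ",
            paste(gap, collapse = ", "))
  n <- nrow(baseline)
  G <- re_covariance(config$re_sd_intercept, config$re_sd_slope, config$re_corr)
  b <- rbvnorm(n, G)
  interval <- config$visit_interval_years
  p_cont <- exp(-config$dropout_hazard_per_year * interval)
  kmax <- floor(config$max_followup_years / interval + 1e-9)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    vals <- as.list(baseline[i, , drop = FALSE])
    f <- function(t) eval_fixed(tab, vals, t)
    times <- 0
    score_mu <- f(0) + b[i, 1]
    k <- 1
    while (k <= kmax) {
      p <- p_cont
      if (config$dropout_mode == "outcome") {
        # lower current score -> higher dropout hazard
        cur <- f(times[length(times)]) + b[i, 1] + b[i, 2] * times[length(times)]
        h <- config$dropout_hazard_per_year *
          exp(0.08 * (attr(tab, "bounds")[2] * 0.8 - cur))
        p <- exp(-h * interval)
      }
      if (stats::runif(1) > p) break
      t_k <- k * interval
      if (config$visit_jitter > 0)
        t_k <- t_k + stats::runif(1, -config$visit_jitter, config$visit_jitter)
      times <- c(times, t_k)
      k <- k + 1
    }
    mu <- f(times) + b[i, 1] + b[i, 2] * times
    y <- mu + stats::rnorm(length(times), 0, config$resid_sd)
    if (config$integer_outcome) y <- round(y)
    y <- clip(y, attr(tab, "bounds"))
    rows[[i]] <- data.frame(subject_id = baseline$subject_id[i],
                            time_years = times, outcome = y,
                            stringsAsFactors = FALSE)
  }
  cohort <- long_cohort(do.call(rbind, rows), baseline, outcome = config$outcome)
  attr(cohort, "random_effects") <-
    data.frame(subject_id = baseline$subject_id, b0 = b[, 1], b1 = b[, 2])
  cohort
}

#' Mask baseline covariates missing-completely-at-random
#'
#' Each covariate value is independently set missing with its configured
#' rate.  Age, sex, baseline MMSE/RAVLT, and diagnosis group are never
#' masked (they were complete in the development cohort).
#'
#' @param cohort a [long_cohort()].
#' @param config a [cohort_config()].
#' @return the cohort with missingness applied.
#' @export
apply_missingness <- function(cohort, config) {
  stopifnot(inherits(cohort, "long_cohort"), inherits(config, "cohort_config"))
  never <- c("subject_id", "group", "age", "sex", "mmse_bl", "ravlt_bl")
  bl <- cohort$baseline
  for (nm in names(config$missing_rates)) {
    if (nm %in% never || !nm %in% names(bl)) next
    rate <- config$missing_rates[[nm]]
    if (rate <= 0) next
    mask <- stats::runif(nrow(bl)) < rate
    bl[[nm]][mask] <- NA
  }
  cohort$baseline <- bl
  cohort
}

#' Simulate a complete synthetic cohort
#'
#' Seeds the RNG from `config$seed` (when set) and runs
#' [generate_baseline()], [generate_trajectories()] and
#' [apply_missingness()] in sequence.  Identical seed and configuration
#' give an identical cohort.
#'
#' @param config a [cohort_config()].
#' @return a [long_cohort()].
#' @examples
#' cfg <- cohort_config("MCI", n_subjects = 50, seed = 1)
#' simulate_cohort(cfg)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  baseline <- generate_baseline(config)
  cohort <- generate_trajectories(baseline, config)
  apply_missingness(cohort, config)
}
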