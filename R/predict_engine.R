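#' Patient profile for individualized prediction
#'
#' One individual's predictor values on the instrument scale.  CSF pTau may
#' be given raw (`ptau`, pg/mL) or already log-transformed (`log_ptau`);
#' when a model expects the log and only the raw value is present it is
#' transformed automatically with an audit note.
#'
#' @param group `"MCI"` or `"dementia"`.
#' @param age years.
#' @param sex `"male"`/`"female"` (or 0/1 with 1 = male).
#' @param mmse_bl baseline MMSE (0-30).
#' @param ravlt_bl baseline RAVLT (0-75), for RAVLT models.
#' @param apoe4 APOE e4 allele count (0, 1, 2).
#' @param abeta CSF amyloid-beta 1-42, pg/mL.
#' @param ptau,log_ptau CSF pTau, raw pg/mL or its natural log.
#' @param tbv,hippocampus MRI total-brain / hippocampal volume, mL.
#' @param ... further covariates (e.g. the full-model clinical variables).
#' @return list of class `patient_profile`.
#' @export
patient_profile <- function(group = c("MCI", "dementia"), age, sex,
                            mmse_bl = NULL, ravlt_bl = NULL, apoe4 = NULL,
                            abeta = NULL, ptau = NULL, log_ptau = NULL,
                            tbv = NULL, hippocampus = NULL, ...) {
  group <- match.arg(group)
  if (!is.null(mmse_bl) && (mmse_bl < 0 || mmse_bl > 30))
    stop_ct("baseline MMSE must be in [0, 30]")
  vals <- c(list(age = age, sex = sex, mmse_bl = mmse_bl, ravlt_bl = ravlt_bl,
                 apoe4 = apoe4, abeta = abeta, ptau = ptau,
                 log_ptau = log_ptau, tbv = tbv, hippocampus = hippocampus),
            list(...))
  vals <- vals[!vapply(vals, is.null, logical(1))]
  num <- vals[!names(vals) %in% c("sex", "bmi_cat", "smoking")]
  if (!all(vapply(num, function(v) is.finite(as.numeric(v)), logical(1))))
    stop_ct("non-finite covariate value in patient profile")
  structure(c(list(group = group), vals), class = "patient_profile")
}

# natural fixed-effect trajectory as a function of time
trajectory_fun <- function(tab, patient) {
  stopifnot(inherits(tab, "coef_table"))
  vals <- if (inherits(patient, "patient_profile")) unclass(patient) else as.list(patient)
  force(vals)
  function(t) eval_fixed(tab, vals, t)
}

#' Predicted mean trajectory for a patient
#'
#' Evaluates the fixed-effect trajectory of a coefficient table at the
#' requested times.  Values are returned unclipped; points outside the
#' instrument bounds are flagged (display-level omission is a rendering
#' choice).  Times beyond the ~5-year range the models were built on are
#' flagged as extrapolation.
#'
#' @param tab a [coef_table()].
#' @param patient a [patient_profile()] (or named list of covariate values).
#' @param times evaluation times in years.
#' @return data frame of class `trajectory` (`time`, `pred`, `clipped`,
#'   `extrapolated`).
#' @examples
#' tab <- reference_coefs("dementia")
#' pt <- patient_profile("dementia", age = 66, sex = "female", mmse_bl = 20,
#'                       apoe4 = 2, abeta = 625, log_ptau = 3.498)
#' predict_mean(tab, pt, times = c(0, 1, 2.3, 5))
#' @export
predict_mean <- function(tab, patient, times) {
  if (any(times < 0)) stop_ct("times must be non-negative")
  times <- sort(times)
  f <- trajectory_fun(tab, patient)
  pred <- f(times)
  notes <- attr(pred, "notes")
  if (length(notes)) message("audit: ", paste(notes, collapse = "; "))
  bounds <- attr(tab, "bounds")
  out <- data.frame(time = times, pred = as.numeric(pred),
                    clipped = pred < bounds[1] | pred > bounds[2],
                    extrapolated = times > 5)
  structure(out, class = c("trajectory", "data.frame"),
            patient = patient, outcome = attr(tab, "outcome"),
            bounds = bounds)
}

#' Hypothetical treatment effect on a decline trajectory
#'
#' A treatment that reduces decline by a fraction `r` is modelled either by
#' time dilation -- the treated patient follows the natural trajectory at a
#' slowed clock, `treated(t) = natural((1 - r) t)`, so any threshold is
#' reached exactly `1/(1 - r)` times later -- or by decline scaling,
#' `treated(t) = natural(0) - (1 - r) (natural(0) - natural(t))`.  Both
#' coincide with the natural trajectory at `r = 0` and at `t = 0`.  Time
#' dilation is the default mechanism.
#'
#' @param reduction fraction `r` in `[0, 1)`, e.g. 0.1, 0.3, 0.5.
#' @param mechanism `"time_dilation"` (default) or `"decline_scaling"`.
#' @return list of class `treatment_spec`.
#' @export
treatment_spec <- function(reduction, mechanism = c("time_dilation", "decline_scaling")) {
  if (reduction < 0 || reduction >= 1) stop_ct("reduction must be in [0, 1)")
  structure(list(reduction = reduction, mechanism = match.arg(mechanism)),
            class = "treatment_spec")
}

#' @rdname treatment_spec
#' @param f natural trajectory function of time (years).
#' @param treatment a [treatment_spec()].
#' @return `apply_treatment` returns the treated trajectory function.
#' @export
apply_treatment <- function(f, treatment) {
  stopifnot(inherits(treatment, "treatment_spec"))
  r <- treatment$reduction
  if (treatment$mechanism == "time_dilation") {
    function(t) f((1 - r) * t)
  } else {
    function(t) f(0) - (1 - r) * (f(0) - f(t))
  }
}

#' Predicted time to reach an outcome threshold
#'
#' Smallest time in `(0, horizon]` at which the (optionally treated)
#' fixed-effect trajectory first crosses the threshold from above, located
#' on a dense grid and refined by bisection to 1e-4 years.  Beyond the
#' ~5-year data range this is an extrapolation of the fitted cubic.
#'
#' @param tab a [coef_table()].
#' @param patient a [patient_profile()].
#' @param threshold outcome value to reach (e.g. MMSE 20 for MCI, 15 for
#'   moderate dementia).
#' @param treatment optional [treatment_spec()].
#' @param horizon search horizon in years (default 20).
#' @return crossing time in years, or `NA` (with attribute
#'   `reached = FALSE`) if the trajectory stays above the threshold.
#' @examples
#' tab <- reference_coefs("MCI")
#' pt <- patient_profile("MCI", age = 66, sex = "male", mmse_bl = 28,
#'                       abeta = 925, log_ptau = 3.415)
#' time_to_threshold(tab, pt, threshold = 20)
#' time_to_threshold(tab, pt, threshold = 20, treatment = treatment_spec(0.3))
#' @export
time_to_threshold <- function(tab, patient, threshold, treatment = NULL,
                              horizon = 20) {
  f <- trajectory_fun(tab, patient)
  g <- if (is.null(treatment)) f else apply_treatment(f, treatment)
  if (g(0) <= threshold)
    stop_ct("threshold exceeded at baseline (predicted ",
            format(g(0), digits = 4), " <= ", threshold, ")")
  grid <- seq(0, horizon, by = 0.01)
  v <- as.numeric(g(grid)) - threshold
  cross <- which(v[-length(v)] > 0 & v[-1] <= 0)
  if (!length(cross)) {
    out <- NA_real_
    attr(out, "reached") <- FALSE
    return(out)
  }
  lo <- grid[cross[1]]; hi <- grid[cross[1] + 1]
  root <- stats::uniroot(function(t) as.numeric(g(t)) - threshold,
                         lower = lo, upper = hi, tol = 1e-5)$root
  out <- root
  attr(out, "reached") <- TRUE
  out
}

#' Random-effect uncertainty band around an individual trajectory
#'
#' Draws `n` random intercept/slope pairs from the estimated random-effect
#' distribution and adds `b0 + b1 t` (raw time) to the mean trajectory,
#' visualising the interindividual variation not explained by the
#' predictors.  Pointwise percentiles of the simulated trajectories form
#' the band; [percentile_of()] ranks any value (e.g. a treated prediction)
#' within the simulated natural distribution at a given time.
#'
#' @param tab a [coef_table()].
#' @param patient a [patient_profile()].
#' @param re_cov 2x2 random-effect covariance (intercept, slope).
#' @param times evaluation grid in years.
#' @param n number of simulated individuals (default 1000; at least 2).
#' @param probs band percentiles (default 2/16/50/84/98).
#' @param resid_var optional residual variance added per draw (default 0:
#'   the band shows random-effect heterogeneity only).
#' @param seed RNG seed.
#' @return object of class `uncertainty_band`: `band` data frame (`time`
#'   and one column per percentile), simulated draws kept for ranking.
#' @export
simulate_individual_band <- function(tab, patient, re_cov, times = seq(0, 5, 0.25),
                                     n = 1000, probs = c(2, 16, 50, 84, 98) / 100,
                                     resid_var = 0, seed = NULL) {
  if (n < 2) stop_ct("need at least 2 simulated individuals")
  ev <- eigen(re_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop_ct("re_cov must be positive semidefinite")
  if (!is.null(seed)) set.seed(seed)
  f <- trajectory_fun(tab, patient)
  mu <- as.numeric(f(times))
  b <- rbvnorm(n, re_cov)
  sims <- matrix(mu, n, length(times), byrow = TRUE) +
    b[, 1] + outer(b[, 2], times)
  if (resid_var > 0)
    sims <- sims + matrix(stats::rnorm(length(sims), 0, sqrt(resid_var)),
                          n, length(times))
  qs <- apply(sims, 2, stats::quantile, probs = probs)
  band <- data.frame(time = times, t(qs))
  names(band) <- c("time", paste0("p", probs * 100))
  structure(list(band = band, mean = mu, times = times, draws = sims,
                 probs = probs),
            class = "uncertainty_band")
}

#' @rdname simulate_individual_band
#' @param band an `uncertainty_band`.
#' @param time time point at which to rank.
#' @param value outcome value to rank within the simulated natural
#'   distribution at `time` (e.g. a treated prediction).
#' @return `percentile_of` returns the percentile (0-100): the share of
#'   simulated natural trajectories lying at or below `value`.
#' @export
percentile_of <- function(band, time, value) {
  stopifnot(inherits(band, "uncertainty_band"))
  j <- which.min(abs(band$times - time))
  if (abs(band$times[j] - time) > 1e-6)
    stop_ct("time ", time, " is not on the simulated grid")
  draws <- band$draws[, j]
  if (stats::sd(draws) == 0)
    return(if (value >= draws[1]) 100 else 0)
  mean(draws <= value) * 100
}

#' Population percentile fan of predicted trajectories
#'
#' For every subject of the fitted cohort the predicted trajectory
#' (fixed effects at the subject's covariates plus the estimated random
#' intercept and slope) is evaluated on a time grid; the requested
#' empirical percentiles across subjects are reported per time point,
#' omitting predictions outside the instrument bounds.
#'
#' @param fit an [fit_lmm()] (or `decline_model`) object.
#' @param cohort cohort whose subjects form the fan; defaults to the
#'   fitting data.
#' @param times grid in years (starting at 0.5 by convention).
#' @param probs percentiles (default 2/16/50/84/98).
#' @return data frame of class `population_fan`: `time`, one column per
#'   percentile, and `n` (subjects inside bounds at that time).
#' @export
population_fan <- function(fit, cohort = NULL, times = seq(0.5, 5, 0.25),
                           probs = c(2, 16, 50, 84, 98) / 100) {
  if (inherits(fit, "decline_model")) {
    tab <- fit$coefficients; re <- fit$blups
    bl <- fit$cohort$baseline
  } else {
    stopifnot(inherits(fit, "lmm_fit"))
    tab <- fit$coefficients
    re <- estimate_blups(fit, cohort)
    bl <- if (is.null(cohort)) {
      ids <- unique(fit$design$subject_id)
      stop_ct("population_fan needs the cohort when given a bare lmm_fit")
    } else cohort$baseline
  }
  if (nrow(bl) == 0) stop_ct("empty cohort")
  bounds <- attr(tab, "bounds")
  preds <- matrix(NA_real_, nrow(bl), length(times))
  for (i in seq_len(nrow(bl))) {
    vals <- as.list(bl[i, , drop = FALSE])
    mu <- as.numeric(eval_fixed(tab, vals, times))
    j <- match(bl$subject_id[i], re$subject_id)
    preds[i, ] <- mu + re$b0[j] + re$b1[j] * times
  }
  out <- data.frame(time = times)
  for (p in probs) out[[paste0("p", p * 100)]] <- NA_real_
  out$n <- NA_integer_
  for (tj in seq_along(times)) {
    v <- preds[, tj]
    v <- v[v >= bounds[1] & v <= bounds[2]]
    out$n[tj] <- length(v)
    if (length(v))
      out[tj, paste0("p", probs * 100)] <- stats::quantile(v, probs = probs)
  }
  structure(out, class = c("population_fan", "data.frame"), bounds = bounds)
}

#' @export
plot.population_fan <- function(x, ...) {
  pc <- grep("^p[0-9]", names(x), value = TRUE)
  graphics::matplot(x$time, as.matrix(x[, pc]), type = "l", lty = 1,
                    xlab = "Years since baseline", ylab = "Predicted outcome",
                    ...)
  graphics::legend("bottomleft", legend = pc, col = seq_along(pc), lty = 1,
                   bty = "n")
  invisible(x)
}

#' @export
plot.uncertainty_band <- function(x, max_draws = 200, ...) {
  sub <- x$draws[seq_len(min(nrow(x$draws), max_draws)), , drop = FALSE]
  graphics::matplot(x$times, t(sub), type = "l", lty = 1,
                    col = grDevices::adjustcolor("steelblue", 0.15),
                    xlab = "Years since baseline", ylab = "Predicted outcome",
                    ...)
  graphics::lines(x$times, x$mean, lwd = 2)
  invisible(x)
}
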