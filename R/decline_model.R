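#' Fit an individualized cognitive-decline prediction model
#'
#' The front door of the package: takes a longitudinal cohort of one
#' diagnosis group and runs the full model-building pipeline -- multiple
#' imputation when baseline covariates are missing, the chosen estimation
#' method (unpenalized, backward selection stabilised across imputed sets,
#' or grouped ridge), and Rubin's-rules pooling -- returning a fitted model
#' whose [coef_table()] drives the prediction engine.
#'
#' Backward selection removes non-forced terms with Wald p at or above
#' `alpha` per imputed set and keeps terms selected in at least half the
#' sets (configurable); the time polynomial and the age and sex main
#' effects are always retained.  Ridge applies local shrinkage in four term
#' groups (time curve, baseline score, other constant effects, time-varying
#' effects).  MCI and mild dementia are modelled separately: the cohort
#' must contain a single diagnosis group.
#'
#' @param cohort a [long_cohort()] (one diagnosis group).
#' @param tier candidate predictor tier: `"base"`, `"biomarker"` (default)
#'   or `"full"`.
#' @param method `"backward"` (default), `"none"` or `"ridge"`.
#' @param impute an [impute_control()]; used when baseline covariates are
#'   missing.
#' @param select a [selection_control()].
#' @param time_center centering constant in years (default 2.3).
#' @param seed master seed; imputation and ridge tuning draw from offsets
#'   of it.
#' @return object of class `decline_model` with components `coefficients`
#'   (pooled [coef_table()]), `re_cov`, `resid_var`, `blups` (first
#'   completed set), `retention` (selection counts, backward only),
#'   `m`, `tier`, `method`, `cohort`.
#' @seealso [predict.decline_model()], [time_to_threshold()],
#'   [population_fan()], [kfold_cv()].
#' @examples
#' cfg <- cohort_config("MCI", n_subjects = 80, seed = 7,
#'                      missing_rates = c(abeta = 0))
#' fit <- decline_model(simulate_cohort(cfg), tier = "base", method = "none")
#' fit
#' @export
decline_model <- function(cohort, tier = c("biomarker", "base", "full"),
                          method = c("backward", "none", "ridge"),
                          impute = impute_control(), select = selection_control(),
                          time_center = 2.3, seed = NULL) {
  stopifnot(inherits(cohort, "long_cohort"))
  tier <- match.arg(tier)
  method <- match.arg(method)
  grp <- unique(cohort$baseline$group)
  if (length(grp) > 1)
    stop_ct("MCI and mild dementia are modelled separately; split the cohort ",
            "by group first (found: ", paste(grp, collapse = ", "), ")")
  terms <- tier_terms(tier, cohort$outcome)
  used <- unique(stats::na.omit(terms$covariate))
  has_na <- any(vapply(used, function(nm) anyNA(cohort$baseline[[nm]]), logical(1)))
  sets <- if (has_na) {
    impute_chained(cohort, impute, seed = if (is.null(seed)) NULL else seed + 1000)
  } else {
    structure(list(cohort), class = "imputed_cohorts")
  }
  retention <- NULL
  if (method == "backward") {
    final_terms <- stability_select(sets, terms, select, time_center)
    retention <- attr(final_terms, "retention")
    fin <- finalize_model(sets, final_terms, time_center)
  } else if (method == "none") {
    fin <- finalize_model(sets, terms, time_center)
  } else {
    fits <- lapply(seq_along(sets), function(s)
      fit_grouped_ridge(build_design(sets[[s]], terms, time_center),
                        seed = if (is.null(seed)) NULL else seed + 2000))
    est <- do.call(rbind, lapply(fits, function(f) f$coefficients$estimate))
    tab <- fits[[1]]$coefficients
    tab$estimate <- colMeans(est)
    fin <- list(coefficients = tab,
                re_cov = Reduce(`+`, lapply(fits, `[[`, "re_cov")) / length(fits),
                resid_var = mean(vapply(fits, `[[`, numeric(1), "resid_var")),
                m = length(sets),
                first_fit = fits[[1]])
  }
  blups <- estimate_blups(fin$first_fit)
  structure(list(coefficients = fin$coefficients, re_cov = fin$re_cov,
                 resid_var = fin$resid_var, blups = blups,
                 retention = retention, m = fin$m, tier = tier,
                 method = method, cohort = sets[[1]],
                 time_center = time_center,
                 n_subjects = nrow(cohort$baseline),
                 n_obs = sum(!is.na(cohort$visits$outcome)),
                 call = match.call()),
            class = "decline_model")
}

#' @export
print.decline_model <- function(x, ...) {
  cat(sprintf("Cognitive-decline prediction model (%s, %s tier, %s)\n",
              attr(x$coefficients, "group"), x$tier, x$method))
  cat(sprintf("  %d subjects, %d observations, pooled over %d data set(s)\n",
              x$n_subjects, x$n_obs, x$m))
  cat(sprintf("  %d fixed-effect terms; RE SDs (%.2f, %.2f), residual SD %.2f\n",
              nrow(x$coefficients), sqrt(x$re_cov[1, 1]), sqrt(x$re_cov[2, 2]),
              sqrt(x$resid_var)))
  invisible(x)
}

#' @export
summary.decline_model <- function(object, ...) {
  structure(list(model = object), class = "summary.decline_model")
}

#' @export
print.summary.decline_model <- function(x, ...) {
  m <- x$model
  print(m)
  print(m$coefficients)
  if (!is.null(m$retention)) {
    cat("Selection retention counts (of", m$m, "sets):\n")
    print(m$retention)
  }
  invisible(x)
}

#' @export
coef.decline_model <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Predict from a fitted decline model
#'
#' With a [patient_profile()] in `newdata`, returns the individualized
#' fixed-effect trajectory at `times` (see [predict_mean()]).  With a
#' [long_cohort()], returns per-observation predictions: marginal (fixed
#' effects only) or conditional (adding the subject's estimated random
#' effects, available for subjects of the fitting data).  `newdata = NULL`
#' predicts the fitting data.
#'
#' @param object a `decline_model`.
#' @param newdata a [patient_profile()], a [long_cohort()], or `NULL`.
#' @param times trajectory times (profile predictions only).
#' @param type `"marginal"` or `"conditional"`.
#' @param ... unused.
#' @export
predict.decline_model <- function(object, newdata = NULL, times = seq(0, 5, 0.5),
                                  type = c("marginal", "conditional"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "patient_profile"))
    return(predict_mean(object$coefficients, newdata, times))
  cohort <- newdata %||% object$cohort
  pred <- predict_cohort(object$coefficients, cohort)
  if (type == "conditional") {
    tab <- object$coefficients
    des <- build_design(cohort, as.data.frame(tab)[tab$role != "intercept", ],
                        object$time_center)
    j <- match(des$subject_id, object$blups$subject_id)
    if (anyNA(j)) stop_ct("conditional predictions need subjects from the fitting data")
    pred <- pred + object$blups$b0[j] + object$blups$b1[j] * des$time
  }
  pred
}

#' @export
fitted.decline_model <- function(object, ...) {
  predict.decline_model(object, type = "conditional")
}

#' @export
residuals.decline_model <- function(object, type = c("conditional", "marginal"), ...) {
  type <- match.arg(type)
  tab <- object$coefficients
  des <- build_design(object$cohort, as.data.frame(tab)[tab$role != "intercept", ],
                      object$time_center)
  des$y - predict.decline_model(object, type = type)
}

#' @export
plot.decline_model <- function(x, times = seq(0.5, 5, 0.25), ...) {
  plot(population_fan(x, times = times), ...)
}

#' Simulate outcome vectors from a fitted decline model
#'
#' Draws new random effects and residual noise at the fitting data's
#' design (fixed effects at each subject's covariates), returning one
#' simulated outcome vector per replicate, rounded and clipped to the
#' instrument bounds.
#'
#' @param object a `decline_model`.
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param ... unused.
#' @export
simulate.decline_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tab <- object$coefficients
  des <- build_design(object$cohort, as.data.frame(tab)[tab$role != "intercept", ],
                      object$time_center)
  mu <- drop(des$X %*% tab$estimate)
  ids <- unique(des$subject_id)
  bounds <- attr(tab, "bounds")
  out <- as.data.frame(replicate(nsim, {
    b <- rbvnorm(length(ids), object$re_cov)
    j <- match(des$subject_id, ids)
    y <- mu + b[j, 1] + b[j, 2] * des$time +
      stats::rnorm(length(mu), 0, sqrt(object$resid_var))
    clip(round(y), bounds)
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
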