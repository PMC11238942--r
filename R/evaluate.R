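#' Fixed-effect predictions for every observation of a cohort
#'
#' Evaluates a coefficient table at each visit row using the subject's
#' baseline covariates (raw, unclipped predictions).
#'
#' @param tab a [coef_table()].
#' @param cohort a [long_cohort()] supplying every covariate the table
#'   references.
#' @return numeric vector aligned with `cohort$visits` rows that carry an
#'   observed outcome.
#' @export
predict_cohort <- function(tab, cohort) {
  stopifnot(inherits(tab, "coef_table"), inherits(cohort, "long_cohort"))
  terms <- as.data.frame(tab)
  need_cols <- unique(stats::na.omit(terms$covariate))
  have <- names(cohort$baseline)
  gap <- setdiff(need_cols, have)
  if (length(gap))
    stop_ct("cohort lacks covariate column(s) required by the model: ",
            paste(gap, collapse = ", "))
  des <- build_design(cohort, terms[terms$role != "intercept", , drop = FALSE],
                      time_center = attr(tab, "time_center"))
  drop(des$X %*% terms$estimate)
}

metric_row <- function(obs, pred, label) {
  err <- obs - pred
  sst <- sum((obs - mean(obs))^2)
  data.frame(fold = label, n = length(obs),
             rmse = sqrt(mean(err^2)),
             mad = stats::median(abs(err)),
             r2 = 1 - sum(err^2) / sst,
             stringsAsFactors = FALSE)
}

#' Subject-level k-fold cross-validation of the modelling pipeline
#'
#' Subjects (not observations) are partitioned into `k` folds; for each
#' fold the chosen pipeline (no penalization, backward selection, or
#' grouped ridge) is trained on the remaining folds and the held-out
#' subjects are scored with fixed effects only -- their random effects are
#' unknowable without peeking at their outcomes.  Out-of-sample RMSE,
#' median absolute deviation of the prediction errors, and R-squared
#' (1 - SSE/SST, SST around the held-out outcome mean, so negative values
#' are possible) are reported per fold and pooled over all held-out
#' observations.
#'
#' @param cohort a complete [long_cohort()] (impute first if needed).
#' @param tier `"base"`, `"biomarker"` or `"full"`.
#' @param method `"none"`, `"backward"` or `"ridge"`.
#' @param k number of folds (default 5).
#' @param seed seed for fold assignment.
#' @param control [selection_control()] for backward selection.
#' @param time_center centering constant.
#' @param include_baseline score baseline observations too (default TRUE;
#'   the models include baseline in the outcome).
#' @param sst_mean `"test"` (default) or `"train"`: the mean around which
#'   SST is computed.
#' @return object of class `cv_metrics`: per-fold data frame plus pooled
#'   row and parameter counts.
#' @export
kfold_cv <- function(cohort, tier = "biomarker",
                     method = c("none", "backward", "ridge"), k = 5,
                     seed = NULL, control = selection_control(),
                     time_center = 2.3, include_baseline = TRUE,
                     sst_mean = c("test", "train")) {
  stopifnot(inherits(cohort, "long_cohort"))
  method <- match.arg(method)
  sst_mean <- match.arg(sst_mean)
  ids <- unique(cohort$baseline$subject_id)
  if (k > length(ids)) stop_ct("k exceeds the number of subjects")
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = length(ids)))
  names(fold) <- ids
  terms <- tier_terms(tier, cohort$outcome)
  rows <- list(); all_obs <- c(); all_pred <- c(); npar <- integer(k)
  for (f in seq_len(k)) {
    train <- subset_cohort(cohort, names(fold)[fold != f])
    test <- subset_cohort(cohort, names(fold)[fold == f])
    tab <- switch(method,
      none = fit_lmm(build_design(train, terms, time_center))$coefficients,
      backward = {
        sel <- backward_select_one(train, terms, control, time_center)
        fit_lmm(build_design(train, sel, time_center))$coefficients
      },
      ridge = fit_grouped_ridge(build_design(train, terms, time_center),
                                seed = if (is.null(seed)) NULL else seed + f
                                )$coefficients)
    npar[f] <- nrow(tab)
    des <- build_design(test, as.data.frame(tab)[tab$role != "intercept", ],
                        time_center)
    pred <- drop(des$X %*% tab$estimate)
    obs <- des$y
    if (!include_baseline) {
      keep <- des$time > 0
      pred <- pred[keep]; obs <- obs[keep]
    }
    err <- obs - pred
    ctr <- if (sst_mean == "test") mean(obs) else mean(train$visits$outcome, na.rm = TRUE)
    rows[[f]] <- data.frame(fold = as.character(f), n = length(obs),
                            rmse = sqrt(mean(err^2)),
                            mad = stats::median(abs(err)),
                            r2 = 1 - sum(err^2) / sum((obs - ctr)^2),
                            stringsAsFactors = FALSE)
    all_obs <- c(all_obs, obs); all_pred <- c(all_pred, pred)
  }
  per_fold <- do.call(rbind, rows)
  pooled <- metric_row(all_obs, all_pred, "pooled")
  structure(list(per_fold = per_fold, pooled = pooled,
                 mean = colMeans(per_fold[, c("rmse", "mad", "r2")]),
                 range = apply(per_fold[, c("rmse", "mad", "r2")], 2, range),
                 n_parameters = npar, tier = tier, method = method, k = k,
                 folds = fold),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("%d-fold subject-level CV, tier %s, method %s\n", x$k, x$tier, x$method))
  cat(sprintf("  parameters: %s (range %d-%d)\n",
              format(mean(x$n_parameters), digits = 3),
              min(x$n_parameters), max(x$n_parameters)))
  for (m in c("rmse", "mad", "r2"))
    cat(sprintf("  %-4s %.3f (fold range %.3f to %.3f)\n", toupper(m),
                x$mean[[m]], x$range[1, m], x$range[2, m]))
  invisible(x)
}

#' Validate a coefficient table on an external cohort
#'
#' Fixed-effect predictions with no refitting; same metric definitions as
#' [kfold_cv()].
#'
#' @param tab a [coef_table()].
#' @param cohort an external [long_cohort()] supplying every covariate the
#'   table references (a missing column raises a schema error naming it).
#' @param include_baseline score baseline rows too (default TRUE).
#' @return one-row metrics data frame (`n`, `rmse`, `mad`, `r2`).
#' @export
external_validate <- function(tab, cohort, include_baseline = TRUE) {
  pred <- predict_cohort(tab, cohort)
  des_terms <- as.data.frame(tab)
  des <- build_design(cohort, des_terms[des_terms$role != "intercept", ],
                      time_center = attr(tab, "time_center"))
  obs <- des$y
  if (!include_baseline) {
    keep <- des$time > 0
    pred <- pred[keep]; obs <- obs[keep]
  }
  metric_row(obs, pred, "external")
}
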