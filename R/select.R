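#' Control parameters for backward selection
#'
#' @param alpha Wald p-value threshold for removal (default 0.10).
#' @param retain_fraction fraction of imputed sets a term must be selected
#'   in to enter the final model (default 0.5, i.e. at least half).
#' @return list of class `selection_control`.
#' @export
selection_control <- function(alpha = 0.10, retain_fraction = 0.5) {
  if (alpha <= 0 || alpha > 1) stop_ct("alpha must be in (0, 1]")
  if (retain_fraction <= 0 || retain_fraction > 1)
    stop_ct("retain_fraction must be in (0, 1]")
  structure(list(alpha = alpha, retain_fraction = retain_fraction),
            class = "selection_control")
}

#' Backward selection on one completed data set
#'
#' Iteratively refits the mixed model and removes the non-forced term with
#' the largest Wald p-value at or above `alpha`, until every removable term
#' has p below `alpha`.  The time polynomial and forced main effects are
#' never removed; a main effect is not removable while its time interaction
#' remains (hierarchy); ties on p break by term name.  A refit failure
#' retains the offending configuration and stops removal (flagged in the
#' audit attribute).
#'
#' @param cohort a complete [long_cohort()].
#' @param terms candidate term set, e.g. [tier_terms()].
#' @param control a [selection_control()].
#' @param time_center centering constant (default 2.3).
#' @return the selected subset of `terms`, with attribute `"audit"`
#'   recording the removal order and p-values.
#' @export
backward_select_one <- function(cohort, terms, control = selection_control(),
                                time_center = 2.3) {
  current <- terms
  audit <- list()
  repeat {
    fit <- tryCatch(fit_lmm(build_design(cohort, current, time_center)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      audit$flag <- paste("refit failed; remaining terms retained:",
                          conditionMessage(fit))
      break
    }
    tab <- fit$coefficients
    has_inter <- current$term[current$role == "interaction"]
    removable <- !current$forced & current$role != "time" &
      !(current$role == "main" & paste0(current$term, ":time_c") %in% has_inter)
    if (!any(removable)) break
    pv <- tab$p[match(current$term, tab$term)]
    pv[is.na(pv)] <- 1  # collinear columns dropped by the solver go first
    cand <- which(removable & pv >= control$alpha)
    if (!length(cand)) break
    worst <- cand[order(-pv[cand], current$term[cand])][1]
    audit[[length(audit) + 1]] <- list(term = current$term[worst],
                                       p = pv[worst])
    current <- current[-worst, , drop = FALSE]
  }
  attr(current, "audit") <- audit
  current
}

#' Stability selection across multiply imputed data sets
#'
#' Runs [backward_select_one()] on each completed data set; a term enters
#' the final model iff it was selected in at least `retain_fraction` of the
#' sets.  Hierarchy is repaired afterwards: the main effect of any
#' surviving interaction is added back, and forced terms are always
#' present.
#'
#' @param cohorts list of completed [long_cohort()]s (an `imputed_cohorts`).
#' @param terms candidate term set.
#' @param control a [selection_control()].
#' @param time_center centering constant.
#' @return final term set with attribute `"retention"` (per-term selection
#'   counts) and `"per_set"` (each set's selection).
#' @export
stability_select <- function(cohorts, terms, control = selection_control(),
                             time_center = 2.3) {
  m <- length(cohorts)
  if (m < 1) stop_ct("need at least one completed data set")
  per_set <- lapply(cohorts, backward_select_one, terms = terms,
                    control = control, time_center = time_center)
  counts <- vapply(terms$term, function(tm)
    sum(vapply(per_set, function(s) tm %in% s$term, logical(1))), numeric(1))
  keep <- terms$forced | counts >= control$retain_fraction * m
  final <- terms[keep, , drop = FALSE]
  # hierarchy repair: interactions pull their main effects back in
  inter <- final$term[final$role == "interaction"]
  need_main <- sub(":time_c$", "", inter)
  add <- setdiff(need_main, final$term)
  if (length(add))
    final <- rbind(final, terms[terms$term %in% add, , drop = FALSE])
  final <- terms[terms$term %in% final$term, , drop = FALSE]  # original order
  attr(final, "retention") <- counts
  attr(final, "per_set") <- lapply(per_set, function(s) s$term)
  final
}

#' Refit the final structure on every set and pool by Rubin's rules
#'
#' Fits the final fixed-effect structure on each completed data set, pools
#' coefficients and their squared standard errors with [pool_rubin()], and
#' averages the random-effect covariance and residual variance across
#' sets.
#'
#' @param cohorts list of completed [long_cohort()]s.
#' @param terms final term set (non-empty).
#' @param time_center centering constant.
#' @return list with `coefficients` (pooled [coef_table()] with `se` and
#'   normal-approximation `p`), `re_cov`, `resid_var`, `m`, and the
#'   per-set fits' pooling detail (`pooled`).
#' @export
finalize_model <- function(cohorts, terms, time_center = 2.3) {
  if (nrow(terms) == 0) stop_ct("final term set is empty")
  fits <- lapply(cohorts, function(ch)
    fit_lmm(build_design(ch, terms, time_center)))
  est <- do.call(rbind, lapply(fits, function(f) f$coefficients$estimate))
  vars <- do.call(rbind, lapply(fits, function(f) f$coefficients$se^2))
  colnames(est) <- colnames(vars) <- fits[[1]]$coefficients$term
  pooled <- pool_rubin(est, vars)
  tab <- fits[[1]]$coefficients
  tab$estimate <- unname(pooled$estimate)
  tab$se <- unname(pooled$se)
  tab$p <- unname(2 * stats::pnorm(-abs(pooled$estimate / pooled$se)))
  re_cov <- Reduce(`+`, lapply(fits, `[[`, "re_cov")) / length(fits)
  resid_var <- mean(vapply(fits, `[[`, numeric(1), "resid_var"))
  list(coefficients = tab, re_cov = re_cov, resid_var = resid_var,
       m = length(cohorts), pooled = pooled, first_fit = fits[[1]])
}
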