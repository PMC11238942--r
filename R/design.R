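#' Candidate model terms for the three prediction-model tiers
#'
#' The base tier holds the cubic time curve plus age, sex and the baseline
#' score, with main effects and linear-time interactions; the biomarker
#' tier adds APOE e4 allele count, CSF amyloid-beta 1-42, log CSF pTau and
#' MRI total-brain and hippocampal volume; the full tier further adds the
#' clinical variables (education years, depression scale, systolic and
#' diastolic blood pressure, BMI category, smoking history).  The time
#' polynomial and the age and sex main effects are forced (never removed
#' by selection); interactions and the remaining mains are selectable.
#'
#' @param tier `"base"`, `"biomarker"` or `"full"`.
#' @param outcome `"mmse"` or `"ravlt"` (chooses the baseline-score term).
#' @return data frame of terms (`term`, `covariate`, `transform`, `level`,
#'   `role`, `forced`).
#' @export
tier_terms <- function(tier = c("base", "biomarker", "full"),
                       outcome = c("mmse", "ravlt")) {
  tier <- match.arg(tier)
  outcome <- match.arg(outcome)
  row <- function(term, covariate, transform = "identity", level = NA_character_,
                  role, forced = FALSE)
    data.frame(term = term, covariate = covariate, transform = transform,
               level = level, role = role, forced = forced,
               stringsAsFactors = FALSE)
  tm <- rbind(row("time_c", NA_character_, role = "time", forced = TRUE),
              row("time_c2", NA_character_, role = "time", forced = TRUE),
              row("time_c3", NA_character_, role = "time", forced = TRUE))
  pair <- function(term, covariate, transform = "identity",
                   level = NA_character_, forced_main = FALSE)
    rbind(row(term, covariate, transform, level, "main", forced_main),
          row(paste0(term, ":time_c"), covariate, transform, level,
              "interaction", FALSE))
  bl_term <- if (outcome == "mmse") "mmse_bl" else "ravlt_bl"
  out <- rbind(tm,
               pair("age", "age", forced_main = TRUE),
               pair("sex_male", "sex", forced_main = TRUE),
               pair(bl_term, bl_term))
  if (tier %in% c("biomarker", "full"))
    out <- rbind(out,
                 pair("apoe4", "apoe4"),
                 pair("abeta", "abeta"),
                 pair("log_ptau", "ptau", transform = "log"),
                 pair("tbv", "tbv"),
                 pair("hippocampus", "hippocampus"))
  if (tier == "full")
    out <- rbind(out,
                 pair("education_years", "education_years"),
                 pair("gds", "gds"),
                 pair("sbp", "sbp"),
                 pair("dbp", "dbp"),
                 pair("bmi_25_30", "bmi_cat", level = "25-30"),
                 pair("bmi_gt30", "bmi_cat", level = ">30"),
                 pair("smoking_former", "smoking", level = "former"),
                 pair("smoking_current", "smoking", level = "current"))
  rownames(out) <- NULL
  out
}

# column of covariate values on the model scale for one term definition
term_column <- function(term_row, data) {
  cov <- term_row$covariate
  if (!cov %in% names(data) && !(cov == "sex"))
    stop_ct("covariate '", cov, "' absent from baseline table")
  x <- data[[cov]]
  if (identical(cov, "sex")) {
    v <- sex_to_male(x)
  } else if (!is.na(term_row$level)) {
    v <- as.numeric(as.character(x) == term_row$level)
    v[is.na(x)] <- NA_real_
  } else if (term_row$transform == "log") {
    if (any(x <= 0, na.rm = TRUE))
      stop_ct("non-positive value of '", cov, "' under log transform")
    v <- log(as.numeric(x))
  } else {
    v <- as.numeric(x)
  }
  v
}

#' Build fixed- and random-effect design matrices
#'
#' Constructs the fixed-effect design for a term set: intercept, centered
#' time polynomial (`t' = t - time_center`, `t'^2`, `t'^3`), covariate main
#' effects on the model scale, and covariate-by-centered-time interactions.
#' The random-effect design per subject is `(1, t)` with raw (uncentered)
#' time.  The response includes the baseline observation.  All covariates a
#' term references must be complete (impute first).
#'
#' @param cohort a [long_cohort()] with complete covariates for `terms`.
#' @param terms term data frame as from [tier_terms()].
#' @param time_center centering constant in years (default 2.3).
#' @return list of class `lmm_design`: `X` (fixed design with intercept),
#'   `y`, `subject_id`, `time`, `terms` (with the intercept row), plus
#'   outcome metadata.
#' @export
build_design <- function(cohort, terms, time_center = 2.3) {
  stopifnot(inherits(cohort, "long_cohort"))
  dat <- merge(cohort$visits, cohort$baseline, by = "subject_id", sort = FALSE)
  dat <- dat[order(dat$subject_id, dat$time_years), , drop = FALSE]
  dat <- dat[!is.na(dat$outcome), , drop = FALSE]
  if (!"forced" %in% names(terms)) terms$forced <- logical(nrow(terms))
  if (!"level" %in% names(terms)) terms$level <- rep(NA_character_, nrow(terms))
  tc <- dat$time_years - time_center
  X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
  main_vals <- list()
  for (i in seq_len(nrow(terms))) {
    tr <- terms[i, ]
    col <- switch(tr$role,
      time = switch(tr$term, time_c = tc, time_c2 = tc^2, time_c3 = tc^3),
      main = {
        v <- term_column(tr, dat)
        main_vals[[tr$term]] <- v
        v
      },
      interaction = {
        base_term <- sub(":time_c$", "", tr$term)
        v <- main_vals[[base_term]] %||% term_column(tr, dat)
        v * tc
      },
      stop_ct("unknown term role: ", tr$role))
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- tr$term
  }
  bad <- colnames(X)[colSums(is.na(X)) > 0]
  if (length(bad))
    stop_ct("missing covariate values in term(s): ",
            paste(bad, collapse = ", "), "; run imputation first")
  base_cols <- c("term", "covariate", "transform", "level", "role", "forced")
  icpt <- data.frame(term = "(Intercept)", covariate = NA_character_,
                     transform = "identity", level = NA_character_,
                     role = "intercept", forced = TRUE, stringsAsFactors = FALSE)
  full_terms <- rbind(icpt, terms[, base_cols, drop = FALSE])
  structure(list(X = X, y = as.numeric(dat$outcome),
                 subject_id = dat$subject_id, time = dat$time_years,
                 terms = full_terms, time_center = time_center,
                 outcome = cohort$outcome, bounds = cohort$bounds,
                 group = cohort$baseline$group[1]),
            class = "lmm_design")
}
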