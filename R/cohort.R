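#' Outcome bounds for the supported cognitive instruments
#'
#' @param outcome `"mmse"` (0-30) or `"ravlt"` (0-75).
#' @return numeric length-2 vector.
#' @export
outcome_bounds <- function(outcome = c("mmse", "ravlt")) {
  outcome <- match.arg(outcome)
  if (outcome == "mmse") c(0, 30) else c(0, 75)
}

#' Long-format longitudinal cohort
#'
#' The unit of all fitting and evaluation: repeated outcome measurements in
#' long format (`subject_id`, `time_years`, `outcome`) joined to a baseline
#' covariate table (one row per subject; `subject_id`, `group`, covariates,
#' possibly missing).  Validation enforces a baseline visit at time 0 for
#' every subject, strictly increasing visit times within subject, outcome
#' values inside the instrument bounds, and referential integrity between
#' the two tables.
#'
#' @param visits data frame with columns `subject_id`, `time_years`,
#'   `outcome`.
#' @param baseline data frame with columns `subject_id`, `group` and one
#'   column per covariate.
#' @param outcome outcome name, sets the instrument bounds.
#' @return An object of class `long_cohort`: a list with elements `visits`,
#'   `baseline`, `outcome`, `bounds`.
#' @export
long_cohort <- function(visits, baseline, outcome = c("mmse", "ravlt")) {
  outcome <- match.arg(outcome)
  bounds <- outcome_bounds(outcome)
  for (col in c("subject_id", "time_years", "outcome"))
    if (!col %in% names(visits))
      stop_ct("visits table lacks mandatory column '", col, "'")
  for (col in c("subject_id", "group"))
    if (!col %in% names(baseline))
      stop_ct("baseline table lacks mandatory column '", col, "'")
  if (anyDuplicated(baseline$subject_id))
    stop_ct("duplicate subject_id in baseline table")
  if (any(visits$time_years < 0))
    stop_ct("negative visit times in rows: ",
            paste(utils::head(which(visits$time_years < 0), 5), collapse = ", "))
  key <- paste(visits$subject_id, visits$time_years)
  if (anyDuplicated(key))
    stop_ct("duplicate (subject, time) rows: ",
            paste(utils::head(key[duplicated(key)], 5), collapse = "; "))
  bad <- !is.na(visits$outcome) &
    (visits$outcome < bounds[1] | visits$outcome > bounds[2])
  if (any(bad))
    stop_ct("outcome outside bounds [", bounds[1], ", ", bounds[2], "] in row(s): ",
            paste(utils::head(which(bad), 5), collapse = ", "))
  orphans <- setdiff(unique(visits$subject_id), baseline$subject_id)
  if (length(orphans))
    stop_ct("subjects in visits absent from baseline table: ",
            paste(utils::head(orphans, 5), collapse = ", "))
  visits <- visits[order(visits$subject_id, visits$time_years), , drop = FALSE]
  rownames(visits) <- NULL
  no_bl <- tapply(visits$time_years, visits$subject_id, function(t) min(t) != 0)
  if (any(no_bl))
    stop_ct("subject(s) without a baseline (time 0) visit: ",
            paste(utils::head(names(no_bl)[no_bl], 5), collapse = ", "))
  structure(list(visits = visits, baseline = baseline,
                 outcome = outcome, bounds = bounds),
            class = "long_cohort")
}

#' @export
print.long_cohort <- function(x, ...) {
  n <- nrow(x$baseline)
  cat(sprintf("Long cohort: %d subjects, %d observations, outcome %s [%g-%g]\n",
              n, nrow(x$visits), x$outcome, x$bounds[1], x$bounds[2]))
  grp <- table(x$baseline$group)
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  nmiss <- vapply(x$baseline, function(col) sum(is.na(col)), integer(1))
  nmiss <- nmiss[nmiss > 0]
  if (length(nmiss))
    cat("  missing baseline values:",
        paste(sprintf("%s=%d", names(nmiss), nmiss), collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a cohort to a set of subjects
#' @param cohort a [long_cohort()].
#' @param subject_ids subjects to keep.
#' @export
subset_cohort <- function(cohort, subject_ids) {
  stopifnot(inherits(cohort, "long_cohort"))
  long_cohort(cohort$visits[cohort$visits$subject_id %in% subject_ids, , drop = FALSE],
              cohort$baseline[cohort$baseline$subject_id %in% subject_ids, , drop = FALSE],
              outcome = cohort$outcome)
}

#' Read and write long cohorts as CSV file pairs
#'
#' The interchange format is a pair of plain CSV files: the long outcome
#' table (`subject_id`, `time_years`, `outcome`) and the baseline covariate
#' table (`subject_id`, `group`, one column per covariate; empty cells are
#' missing values).
#'
#' @param visits_path,baseline_path CSV file paths.
#' @param outcome outcome name (sets the bounds used for validation).
#' @return `read_cohort` returns a validated [long_cohort()]; `write_cohort`
#'   returns the paths invisibly.
#' @export
read_cohort <- function(visits_path, baseline_path, outcome = c("mmse", "ravlt")) {
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  baseline <- utils::read.csv(baseline_path, stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))
  long_cohort(visits, baseline, outcome = match.arg(outcome))
}

#' @rdname read_cohort
#' @param cohort a [long_cohort()].
#' @export
write_cohort <- function(cohort, visits_path, baseline_path) {
  stopifnot(inherits(cohort, "long_cohort"))
  utils::write.csv(cohort$visits, visits_path, row.names = FALSE, na = "")
  utils::write.csv(cohort$baseline, baseline_path, row.names = FALSE, na = "")
  invisible(c(visits_path, baseline_path))
}
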