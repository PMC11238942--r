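#' Coefficient tables for trajectory prediction
#'
#' A `coef_table` is the portable artifact of model building and the sole
#' input the prediction engine needs: a set of named fixed-effect estimates
#' (intercept, cubic time curve, covariate main effects, covariate-by-time
#' interactions) together with the outcome bounds and the time-centering
#' constant.  Time enters the fixed effects centered, `t' = t - time_center`,
#' and interaction terms multiply the *centered* time, so that at
#' `t = time_center` the prediction reduces to the intercept plus the
#' covariate main effects.
#'
#' @param terms data frame with columns `term`, `covariate`, `transform`
#'   (`"identity"` or `"log"`), `role` (`"intercept"`, `"time"`, `"main"`,
#'   `"interaction"`), `estimate` and optionally `se`, `p`, `level`.
#' @param group diagnosis group the model was built in, `"MCI"` or
#'   `"dementia"`.
#' @param outcome outcome name, `"mmse"` or `"ravlt"`.
#' @param bounds numeric length-2 vector of instrument bounds.
#' @param time_center years subtracted from time before building the fixed
#'   time polynomial and interactions.
#' @return An object of class `coef_table` (a data frame with metadata
#'   attributes `group`, `outcome`, `bounds`, `time_center`).
#' @seealso [reference_coefs()] for the shipped reference models,
#'   [predict_mean()] for trajectory evaluation.
#' @export
coef_table <- function(terms, group, outcome = "mmse",
                       bounds = outcome_bounds(outcome), time_center = 2.3) {
  stopifnot(is.data.frame(terms))
  needed <- c("term", "covariate", "transform", "role", "estimate")
  missing_cols <- setdiff(needed, names(terms))
  if (length(missing_cols))
    stop_ct("coef_table terms lack columns: ", paste(missing_cols, collapse = ", "))
  if (!"se" %in% names(terms)) terms$se <- NA_real_
  if (!"(Intercept)" %in% terms$term)
    stop_ct("coef_table must contain an '(Intercept)' term")
  if (!is_scalar_num(time_center))
    stop_ct("time_center must be a finite number")
  # hierarchy: every interaction needs its main effect
  inter <- terms[terms$role == "interaction", ]
  mains <- terms$covariate[terms$role == "main"]
  orphan <- setdiff(inter$covariate, mains)
  if (length(orphan))
    stop_ct("interaction term(s) without a main effect: ",
            paste(orphan, collapse = ", "))
  structure(terms,
            class = c("coef_table", "data.frame"),
            group = group, outcome = outcome,
            bounds = as.numeric(bounds), time_center = time_center)
}

#' @export
print.coef_table <- function(x, ...) {
  cat(sprintf("Coefficient table: %s, outcome %s (bounds %g-%g), time centered by %g\n",
              attr(x, "group"), attr(x, "outcome"),
              attr(x, "bounds")[1], attr(x, "bounds")[2], attr(x, "time_center")))
  print.data.frame(as.data.frame(x)[, intersect(c("term", "estimate", "se", "p"), names(x))],
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' Reference prediction models for amyloid-positive MCI and mild dementia
#'
#' Loads the reference backward-selected biomarker coefficient tables for
#' MMSE decline shipped with the package (one per diagnosis group).  These
#' are the published pooled fixed-effect estimates from a large tertiary
#' memory-clinic cohort of amyloid-positive patients; time is centered by
#' subtracting 2.3 years and interactions multiply centered time.
#'
#' @param group `"MCI"` or `"dementia"`.
#' @return A [coef_table()].
#' @examples
#' tab <- reference_coefs("MCI")
#' predict_mean(tab, patient_profile("MCI", age = 66, sex = "male",
#'   mmse_bl = 27, abeta = 796.22, log_ptau = 3.415), times = 0:5)
#' @export
reference_coefs <- function(group = c("MCI", "dementia")) {
  group <- match.arg(group)
  file <- if (group == "MCI") "coefs_mci_mmse_v1.json" else "coefs_dementia_mmse_v1.json"
  path <- system.file("extdata", file, package = "cogtraj", mustWork = TRUE)
  read_coef_table(path)
}

#' Read or write a coefficient table as JSON
#'
#' @param path file path.
#' @return `read_coef_table` returns a [coef_table()]; `write_coef_table`
#'   returns `path` invisibly.
#' @export
read_coef_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- as.data.frame(obj$terms, stringsAsFactors = FALSE)
  terms$covariate <- as.character(terms$covariate)
  terms$covariate[terms$covariate %in% c("NULL", "NA")] <- NA_character_
  coef_table(terms, group = obj$group, outcome = obj$outcome,
             bounds = obj$bounds, time_center = obj$time_center)
}

#' @rdname read_coef_table
#' @param tab a [coef_table()].
#' @export
write_coef_table <- function(tab, path) {
  stopifnot(inherits(tab, "coef_table"))
  obj <- list(group = attr(tab, "group"), outcome = attr(tab, "outcome"),
              bounds = attr(tab, "bounds"), time_center = attr(tab, "time_center"),
              terms = as.data.frame(tab))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

# Resolve the value of each main-effect term for one set of covariate values
# (a patient profile or one baseline-table row).  Returns a named vector over
# terms with role "main"; interactions reuse the same values.  Handles the
# log transform (accepting either the raw or pre-transformed covariate) and
# sex encoding.  `values` is a named list.
term_values <- function(tab, values) {
  mains <- tab[tab$role == "main", , drop = FALSE]
  out <- numeric(nrow(mains))
  names(out) <- mains$term
  notes <- character(0)
  for (i in seq_len(nrow(mains))) {
    cov <- mains$covariate[i]
    tr <- mains$transform[i]
    lev <- if ("level" %in% names(mains)) mains$level[i] else NA
    if (identical(cov, "sex")) {
      v <- sex_to_male(values[["sex"]])
    } else if (!is.na(lev) && !is.null(lev) && nzchar(as.character(lev)) &&
               !identical(as.character(lev), "NA")) {
      raw <- values[[cov]]
      v <- as.numeric(as.character(raw) == as.character(lev))
    } else if (tr == "log") {
      pre <- values[[paste0("log_", cov)]]
      if (!is.null(pre) && !is.na(pre)) {
        v <- as.numeric(pre)
      } else {
        raw <- values[[cov]]
        if (is.null(raw) || is.na(raw))
          stop_ct("missing covariate for term '", mains$term[i], "': ", cov)
        if (any(raw <= 0))
          stop_ct("covariate '", cov, "' must be strictly positive for log transform")
        v <- log(as.numeric(raw))
        notes <- c(notes, sprintf("%s supplied on instrument scale; log applied", cov))
      }
    } else {
      v <- values[[cov]]
    }
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop_ct("missing covariate for term '", mains$term[i], "': ", cov)
    out[i] <- as.numeric(v)
  }
  attr(out, "notes") <- notes
  out
}

# Fixed-effect prediction at times `t` for one set of covariate values.
# Returns the raw (unclipped) predictions.
eval_fixed <- function(tab, values, times) {
  tc <- times - attr(tab, "time_center")
  est <- stats::setNames(tab$estimate, tab$term)
  vals <- term_values(tab, values)
  pred <- rep(est[["(Intercept)"]], length(times))
  for (nm in c("time_c", "time_c2", "time_c3")) {
    if (nm %in% names(est)) {
      pw <- switch(nm, time_c = 1, time_c2 = 2, time_c3 = 3)
      pred <- pred + est[[nm]] * tc^pw
    }
  }
  mains <- tab[tab$role == "main", , drop = FALSE]
  if (nrow(mains)) pred <- pred + sum(est[mains$term] * vals[mains$term])
  inter <- tab[tab$role == "interaction", , drop = FALSE]
  if (nrow(inter)) {
    main_of <- sub(":time_c$", "", inter$term)
    if (!all(main_of %in% names(vals)))
      stop_ct("interaction term(s) not matching a main effect: ",
              paste(inter$term[!main_of %in% names(vals)], collapse = ", "))
    # interactions multiply centered time: contribution is linear in tc
    slope <- sum(est[inter$term] * vals[main_of])
    pred <- pred + slope * tc
  }
  attr(pred, "notes") <- attr(vals, "notes")
  pred
}
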