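#' Control parameters for multiple imputation
#'
#' @param m number of imputed data sets (default 25).
#' @param n_iter chained-equation sweeps per set (default 10).
#' @param cor_threshold minimal absolute pairwise-complete correlation for a
#'   covariate to act as a donor predictor (default 0.05).
#' @param k_donors donor pool size for predictive-mean matching (default 5).
#' @return list of class `impute_control`.
#' @export
impute_control <- function(m = 25, n_iter = 10, cor_threshold = 0.05, k_donors = 5) {
  if (m < 1) stop_ct("m must be >= 1")
  if (cor_threshold < 0) stop_ct("cor_threshold must be >= 0")
  if (k_donors < 1) stop_ct("k_donors must be >= 1")
  structure(list(m = as.integer(m), n_iter = as.integer(n_iter),
                 cor_threshold = cor_threshold, k_donors = as.integer(k_donors)),
            class = "impute_control")
}

# numeric coding of a baseline table for the correlation screen: factors and
# characters become indicator columns (per non-first level), numerics pass
# through.  Returns a matrix plus a map from column to source covariate.
numeric_code <- function(baseline, cols) {
  mats <- list(); map <- character(0)
  for (nm in cols) {
    x <- baseline[[nm]]
    if (is.numeric(x)) {
      mats[[nm]] <- matrix(x, ncol = 1, dimnames = list(NULL, nm))
      map <- c(map, stats::setNames(nm, nm))
    } else {
      x <- as.factor(x)
      lev <- levels(x)
      for (l in lev[-1]) {
        cn <- paste0(nm, "::", l)
        mats[[cn]] <- matrix(as.numeric(x == l), ncol = 1,
                             dimnames = list(NULL, cn))
        map <- c(map, stats::setNames(nm, cn))
      }
    }
  }
  list(mat = do.call(cbind, mats), map = map)
}

#' Select donor predictors for imputing one covariate
#'
#' Returns the covariates whose absolute pairwise-complete correlation with
#' the target is at least `threshold`; the diagnosis group is always
#' included regardless of its screen correlation.  Categorical variables
#' enter the screen through indicator coding.
#'
#' @param baseline baseline covariate table (data frame).
#' @param target name of the covariate to be imputed.
#' @param threshold minimal absolute correlation (default 0.05).
#' @return character vector of covariate names (always containing
#'   `"group"`).
#' @export
select_donor_variables <- function(baseline, target, threshold = 0.05) {
  if (!target %in% names(baseline)) stop_ct("unknown target covariate: ", target)
  ty <- baseline[[target]]
  if (all(is.na(ty)))
    stop_ct("target covariate '", target, "' has no observed values")
  cand <- setdiff(names(baseline), c("subject_id", "group", target))
  tcode <- numeric_code(baseline, target)
  ccode <- numeric_code(baseline, cand)
  keep <- character(0)
  if (!is.null(ccode$mat)) {
    for (j in seq_len(ncol(ccode$mat))) {
      r <- suppressWarnings(
        stats::cor(tcode$mat, ccode$mat[, j], use = "pairwise.complete.obs"))
      if (any(abs(r) >= threshold, na.rm = TRUE))
        keep <- c(keep, ccode$map[[colnames(ccode$mat)[j]]])
    }
  }
  unique(c("group", keep))
}

# Bayesian-flavoured linear regression draw + predictive-mean matching, the
# standard continuous-variable engine of chained-equation imputation.
# Returns imputed values for the missing rows (always observed donor values).
pmm_impute <- function(y, X_obs, X_mis, k) {
  X_obs <- cbind(1, X_obs); X_mis <- cbind(1, X_mis)
  qrX <- qr(X_obs)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]; X_mis <- X_mis[, keep, drop = FALSE]
  n <- nrow(X_obs); p <- ncol(X_obs)
  XtX <- crossprod(X_obs)
  ridge <- diag(p) * max(1e-8, 1e-8 * mean(diag(XtX)))
  V <- solve(XtX + ridge)
  beta_hat <- V %*% crossprod(X_obs, y)
  res <- y - X_obs %*% beta_hat
  df <- max(n - p, 1)
  sigma2_star <- sum(res^2) / stats::rchisq(1, df)
  beta_star <- beta_hat +
    t(chol((V + t(V)) / 2)) %*% stats::rnorm(p) * sqrt(sigma2_star)
  pred_obs <- drop(X_obs %*% beta_hat)
  pred_mis <- drop(X_mis %*% beta_star)
  vapply(pred_mis, function(pm) {
    d <- abs(pred_obs - pm)
    pool <- order(d)[seq_len(min(k, length(d)))]
    y[sample(pool, 1)]
  }, numeric(1))
}

# categorical draw: multinomial logistic fit on observed rows, sample the
# missing categories from predicted probabilities (binary via glm).
cat_impute <- function(y, df_obs, df_mis) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) return(rep(as.character(levels(y)[1]), nrow(df_mis)))
  if (nlevels(y) == 2) {
    fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df_obs),
                                       family = stats::binomial()))
    p1 <- stats::predict(fit, newdata = df_mis, type = "response")
    as.character(ifelse(stats::runif(length(p1)) < p1, levels(y)[2], levels(y)[1]))
  } else {
    capture <- utils::capture.output(
      fit <- nnet::multinom(y ~ ., data = cbind(y = y, df_obs), trace = FALSE))
    pr <- stats::predict(fit, newdata = df_mis, type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = nrow(df_mis))
    apply(pr, 1, function(p) sample(levels(y), 1, prob = p))
  }
}

#' Multiple imputation by chained equations
#'
#' Fills missing baseline covariates in `m` independent chained-equation
#' sweeps: continuous covariates by predictive-mean matching (`k_donors`
#' nearest observed donors on the linear predictor), categorical ones by
#' (multinomial) logistic draws.  Donor predictors are screened per target
#' by [select_donor_variables()].  Observed values are never altered and
#' outcomes are never imputed (the models use observed scores only).
#' Convergence is monitored through the drift of per-variable chain means
#' over the last three sweeps (reported in the manifest attribute).
#'
#' @param cohort a [long_cohort()] with complete age, sex, baseline score
#'   and diagnosis.
#' @param control an [impute_control()].
#' @param seed integer; each imputed set runs on seed `seed + set index`.
#' @return list of `m` completed [long_cohort()]s, class `imputed_cohorts`,
#'   with a `manifest` attribute (seed, m, donor lists, chain-mean drift).
#' @export
impute_chained <- function(cohort, control = impute_control(), seed = NULL) {
  stopifnot(inherits(cohort, "long_cohort"))
  bl <- cohort$baseline
  miss_cols <- names(bl)[vapply(bl, anyNA, logical(1))]
  if (length(miss_cols) == 0) {
    out <- rep(list(cohort), control$m)
    attr(out, "manifest") <- list(seed = seed, m = control$m, donors = list(),
                                  note = "no missing values; identical copies")
    class(out) <- "imputed_cohorts"
    return(out)
  }
  few <- miss_cols[vapply(miss_cols, function(nm) sum(!is.na(bl[[nm]])) < 10, logical(1))]
  if (length(few))
    stop_ct("covariate(s) with fewer than 10 observed values: ",
            paste(few, collapse = ", "), "; exclude them before imputing")
  # impute in order of increasing missingness
  miss_cols <- miss_cols[order(vapply(miss_cols, function(nm) sum(is.na(bl[[nm]])), numeric(1)))]
  donors <- lapply(stats::setNames(miss_cols, miss_cols), function(nm)
    select_donor_variables(bl, nm, control$cor_threshold))
  sets <- vector("list", control$m)
  drift <- matrix(NA_real_, control$m, length(miss_cols),
                  dimnames = list(NULL, miss_cols))
  for (s in seq_len(control$m)) {
    if (!is.null(seed)) set.seed(seed + s)
    cur <- bl
    # initial fill: random draws from the observed values
    for (nm in miss_cols) {
      nas <- is.na(cur[[nm]])
      cur[[nm]][nas] <- sample(cur[[nm]][!nas], sum(nas), replace = TRUE)
    }
    trace <- matrix(NA_real_, control$n_iter, length(miss_cols),
                    dimnames = list(NULL, miss_cols))
    for (it in seq_len(control$n_iter)) {
      for (nm in miss_cols) {
        nas <- is.na(bl[[nm]])
        dvars <- donors[[nm]]
        code <- numeric_code(cur, dvars)
        Xall <- code$mat
        # drop constant columns (e.g. single-level group)
        keep <- apply(Xall, 2, function(z) stats::sd(z) > 0)
        Xall <- Xall[, keep, drop = FALSE]
        if (is.numeric(bl[[nm]])) {
          imp <- if (ncol(Xall) == 0)
            sample(bl[[nm]][!nas], sum(nas), replace = TRUE)
          else
            pmm_impute(bl[[nm]][!nas], Xall[!nas, , drop = FALSE],
                       Xall[nas, , drop = FALSE], control$k_donors)
          cur[[nm]][nas] <- imp
          trace[it, nm] <- mean(imp)
        } else {
          dfX <- as.data.frame(Xall)
          names(dfX) <- make.names(names(dfX))
          imp <- cat_impute(bl[[nm]][!nas], dfX[!nas, , drop = FALSE],
                            dfX[nas, , drop = FALSE])
          cur[[nm]][nas] <- imp
          trace[it, nm] <- mean(imp == imp[1])
        }
      }
    }
    if (control$n_iter >= 3) {
      last3 <- trace[(control$n_iter - 2):control$n_iter, , drop = FALSE]
      drift[s, ] <- apply(last3, 2, function(z)
        (max(z) - min(z)) / max(abs(mean(z)), 1e-8))
    }
    sets[[s]] <- long_cohort(cohort$visits, cur, outcome = cohort$outcome)
  }
  attr(sets, "manifest") <- list(seed = seed, m = control$m, donors = donors,
                                 chain_mean_drift = drift)
  class(sets) <- "imputed_cohorts"
  sets
}

#' Pool estimates across imputed data sets by Rubin's rules
#'
#' Pooled estimate is the mean of the per-set estimates; total variance is
#' the mean within-set variance plus `(1 + 1/m)` times the between-set
#' variance.  Degrees of freedom follow the classical large-sample formula,
#' or the Barnard-Rubin small-sample adjustment when the complete-data
#' degrees of freedom `dfcom` are supplied.
#'
#' @param estimates numeric matrix (`m` rows, one column per parameter) or
#'   vector of per-set estimates; column names must agree across sets.
#' @param variances matrix/vector of the corresponding squared standard
#'   errors.
#' @param dfcom optional complete-data degrees of freedom.
#' @return list with `estimate`, `variance`, `se`, `df`, `between`,
#'   `within`, `m`.
#' @examples
#' pool_rubin(c(1, 2, 3), c(0.1, 0.1, 0.1))  # estimate 2, variance 1.4333
#' @export
pool_rubin <- function(estimates, variances, dfcom = NULL) {
  if (is.vector(estimates)) estimates <- matrix(estimates, ncol = 1)
  if (is.vector(variances)) variances <- matrix(variances, ncol = 1)
  if (!is.null(colnames(estimates)) && !is.null(colnames(variances)) &&
      !identical(colnames(estimates), colnames(variances)))
    stop_ct("estimate and variance parameter names differ")
  if (!all(dim(estimates) == dim(variances)))
    stop_ct("estimates and variances must have matching dimensions")
  m <- nrow(estimates)
  if (m < 1) stop_ct("need at least one set of estimates")
  qbar <- colMeans(estimates)
  W <- colMeans(variances)
  B <- if (m > 1) apply(estimates, 2, stats::var) else rep(0, ncol(estimates))
  Tvar <- W + (1 + 1 / m) * B
  if (m > 1) {
    r <- (1 + 1 / m) * B / W
    df <- (m - 1) * (1 + 1 / r)^2
    df[B == 0] <- Inf
    if (!is.null(dfcom)) {
      lambda <- (1 + 1 / m) * B / Tvar
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- ifelse(B == 0, df_obs, 1 / (1 / df + 1 / df_obs))
    }
  } else {
    df <- rep(if (is.null(dfcom)) Inf else dfcom, ncol(estimates))
  }
  list(estimate = qbar, variance = Tvar, se = sqrt(Tvar), df = df,
       between = B, within = W, m = m)
}
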