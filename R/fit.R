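#' Fit the random-intercept/slope linear mixed model by REML
#'
#' Fits the longitudinal model `y = X beta + b0_i + b1_i t + e` with an
#' unstructured 2x2 random-effect covariance and i.i.d. residuals,
#' maximising the restricted likelihood (through `lme4::lmer`).  Wald
#' standard errors and normal-approximation p-values are attached per
#' coefficient.
#'
#' @param design an [build_design()] bundle.
#' @param random `"intercept_slope"` (default) or `"intercept"` only.
#' @param reml fit by REML (default) or ML.
#' @return object of class `lmm_fit`: `coefficients` (a [coef_table()] with
#'   `estimate`, `se`, `p`), `re_cov` (2x2, on the raw-time scale),
#'   `resid_var`, `logLik`, `n_subjects`, `n_obs`, and the design metadata.
#' @export
fit_lmm <- function(design, random = c("intercept_slope", "intercept"),
                    reml = TRUE) {
  stopifnot(inherits(design, "lmm_design"))
  random <- match.arg(random)
  X <- design$X
  p <- ncol(X)
  dat <- data.frame(.y = design$y, .time = design$time,
                    .subj = factor(design$subject_id))
  xn <- paste0(".x", seq_len(p))
  for (j in seq_len(p)) dat[[xn[j]]] <- X[, j]
  re <- if (random == "intercept_slope") "(1 + .time | .subj)" else "(1 | .subj)"
  form <- stats::as.formula(paste0(".y ~ 0 + ", paste(xn, collapse = " + "),
                                   " + ", re))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = dat, REML = reml, control = ctrl)))
  # collinear columns are dropped by the solver; their coefficients are
  # reported as 0 with NA uncertainty
  fe <- lme4::fixef(fit)
  kept <- match(names(fe), xn)
  beta <- stats::setNames(rep(0, p), colnames(X))
  se <- stats::setNames(rep(NA_real_, p), colnames(X))
  beta[kept] <- fe
  se[kept] <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  vc <- lme4::VarCorr(fit)
  if (random == "intercept_slope") {
    G <- as.matrix(vc$.subj)[1:2, 1:2]
  } else {
    G <- matrix(c(as.numeric(vc$.subj), 0, 0, 0), 2, 2)
  }
  dimnames(G) <- list(c("intercept", "slope"), c("intercept", "slope"))
  terms <- design$terms
  terms$estimate <- unname(beta[terms$term])
  terms$se <- unname(se[terms$term])
  terms$p <- unname(pval[terms$term])
  tab <- coef_table(terms, group = design$group, outcome = design$outcome,
                    bounds = design$bounds, time_center = design$time_center)
  structure(list(coefficients = tab, re_cov = G,
                 resid_var = stats::sigma(fit)^2,
                 logLik = as.numeric(stats::logLik(fit)),
                 n_subjects = length(unique(design$subject_id)),
                 n_obs = length(design$y),
                 design = design, random = random,
                 merMod = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept/slope LMM (%s): %d subjects, %d observations\n",
              attr(x$coefficients, "group"), x$n_subjects, x$n_obs))
  cat(sprintf("  residual SD %.3f; RE SDs (%.3f, %.3f), corr %.3f; REML logLik %.1f\n",
              sqrt(x$resid_var), sqrt(x$re_cov[1, 1]), sqrt(x$re_cov[2, 2]),
              stats::cov2cor(x$re_cov + diag(1e-12, 2))[1, 2], x$logLik))
  print(x$coefficients)
  invisible(x)
}

#' Empirical-Bayes random-effect estimates (BLUPs)
#'
#' Posterior means of each subject's random intercept and slope given the
#' fitted variance components: `b_i = G Z_i' V_i^{-1} (y_i - X_i beta)`
#' with `Z_i = (1, t)` and `V_i = Z_i G Z_i' + sigma^2 I`.
#'
#' @param fit an [fit_lmm()] object.
#' @param cohort optional [long_cohort()] to score; defaults to the fitting
#'   data.  Unknown subjects (no observations) raise an error.
#' @return data frame `subject_id`, `b0`, `b1`.
#' @export
estimate_blups <- function(fit, cohort = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (is.null(cohort)) {
    des <- fit$design
  } else {
    terms <- fit$coefficients
    des <- build_design(cohort, as.data.frame(terms)[terms$role != "intercept", ],
                        time_center = attr(terms, "time_center"))
  }
  beta <- fit$coefficients$estimate
  resid <- des$y - drop(des$X %*% beta)
  G <- fit$re_cov
  s2 <- fit$resid_var
  ids <- unique(des$subject_id)
  out <- data.frame(subject_id = ids, b0 = NA_real_, b1 = NA_real_)
  for (i in seq_along(ids)) {
    sel <- des$subject_id == ids[i]
    Z <- cbind(1, des$time[sel])
    V <- Z %*% G %*% t(Z) + diag(s2, sum(sel))
    b <- G %*% t(Z) %*% solve(V, resid[sel])
    out$b0[i] <- b[1]; out$b1[i] <- b[2]
  }
  out
}

# default ridge penalty groups for a term set: the cubic time curve, the
# baseline score main effect, other time-constant mains, and the
# time-varying interactions.  Intercept is never penalized.
ridge_groups <- function(terms) {
  grp <- rep(NA_character_, nrow(terms))
  grp[terms$role == "time"] <- "time_curve"
  bl <- terms$role == "main" & terms$term %in% c("mmse_bl", "ravlt_bl")
  grp[bl] <- "baseline_score"
  grp[terms$role == "main" & !bl] <- "constant"
  grp[terms$role == "interaction"] <- "time_varying"
  grp
}

# whitened, standardized normal equations for penalized GLS given variance
# components; returns pieces to solve for any lambda
ridge_workspace <- function(design, G, s2) {
  X <- design$X
  p <- ncol(X)
  ctr <- c(0, colMeans(X[, -1, drop = FALSE]))
  scl <- c(1, apply(X[, -1, drop = FALSE], 2, stats::sd))
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  Xs[, 1] <- 1
  ids <- unique(design$subject_id)
  A <- matrix(0, p, p); bvec <- numeric(p)
  for (id in ids) {
    sel <- design$subject_id == id
    Z <- cbind(1, design$time[sel])
    V <- Z %*% G %*% t(Z) + diag(s2, sum(sel))
    L <- chol(V)
    Xi <- backsolve(L, Xs[sel, , drop = FALSE], transpose = TRUE)
    yi <- backsolve(L, design$y[sel], transpose = TRUE)
    A <- A + crossprod(Xi)
    bvec <- bvec + crossprod(Xi, yi)
  }
  list(A = A, b = bvec, ctr = ctr, scl = scl, p = p)
}

ridge_solve <- function(ws, lam_col) {
  beta_s <- solve(ws$A + diag(lam_col, ws$p), ws$b)
  # back-transform to the original scale
  beta <- beta_s / ws$scl
  beta[1] <- beta_s[1] - sum(ws$ctr[-1] * beta_s[-1] / ws$scl[-1])
  drop(beta)
}

#' Grouped ridge shrinkage of the fixed effects
#'
#' Penalized fit of the fixed effects with local shrinkage in four term
#' groups -- the cubic time curve, the baseline score, the other
#' time-constant effects, and the linear time-varying effects -- each with
#' its own penalty `lambda_g`.  Variance components are fixed at their
#' unpenalized REML estimates; covariates are standardized internally and
#' the estimates returned on the original scale, so `lambda = 0`
#' reproduces the unpenalized generalized-least-squares fit exactly.  When
#' `lambda` is `NULL` it is tuned by inner subject-level cross-validated
#' prediction error over a log-spaced grid (a common value first, then one
#' per-group refinement pass).
#'
#' @param design an [build_design()] bundle.
#' @param lambda optional named vector of penalties for the groups
#'   `time_curve`, `baseline_score`, `constant`, `time_varying`.
#' @param nlambda grid size for tuning (default 20).
#' @param cv_folds inner folds (default 5).
#' @param seed seed for the inner fold assignment.
#' @return an `lmm_fit`-like object with ridge coefficients (`se`/`p` are
#'   `NA`: the reference models report them only for backward selection)
#'   plus the chosen `lambda`.
#' @export
fit_grouped_ridge <- function(design, lambda = NULL, nlambda = 20,
                              cv_folds = 5, seed = NULL) {
  stopifnot(inherits(design, "lmm_design"))
  if (stats::var(design$y) == 0)
    stop_ct("outcome has zero variance; nothing to fit")
  base <- fit_lmm(design)
  G <- base$re_cov; s2 <- base$resid_var
  terms <- base$coefficients
  grp <- ridge_groups(as.data.frame(terms))
  gnames <- c("time_curve", "baseline_score", "constant", "time_varying")
  ws <- ridge_workspace(design, G, s2)
  lam_col <- function(lam) {
    v <- rep(0, ws$p)
    for (g in gnames) v[which(grp == g)] <- lam[[g]] %||% 0
    v
  }
  if (is.null(lambda)) {
    if (!is.null(seed)) set.seed(seed)
    ids <- unique(design$subject_id)
    fold <- sample(rep(seq_len(cv_folds), length.out = length(ids)))
    names(fold) <- ids
    grid <- 10^seq(-3, 4, length.out = nlambda)
    cv_err <- function(lam) {
      err <- 0
      for (f in seq_len(cv_folds)) {
        tr <- names(fold)[fold != f]
        sel <- design$subject_id %in% tr
        dtr <- design; dtr$X <- design$X[sel, , drop = FALSE]
        dtr$y <- design$y[sel]; dtr$subject_id <- design$subject_id[sel]
        dtr$time <- design$time[sel]
        wtr <- ridge_workspace(dtr, G, s2)
        beta <- ridge_solve(wtr, lam_col(lam))
        pred <- drop(design$X[!sel, , drop = FALSE] %*% beta)
        err <- err + sum((design$y[!sel] - pred)^2)
      }
      err
    }
    common <- vapply(grid, function(l)
      cv_err(stats::setNames(as.list(rep(l, 4)), gnames)), numeric(1))
    lam <- stats::setNames(as.list(rep(grid[which.min(common)], 4)), gnames)
    for (g in gnames) {  # one per-group refinement pass
      errs <- vapply(grid, function(l) {
        lam2 <- lam; lam2[[g]] <- l; cv_err(lam2)
      }, numeric(1))
      lam[[g]] <- grid[which.min(errs)]
    }
    lambda <- unlist(lam)
  } else {
    if (is.null(names(lambda))) names(lambda) <- gnames[seq_along(lambda)]
    if (any(lambda < 0)) stop_ct("lambda must be >= 0")
  }
  beta <- ridge_solve(ws, lam_col(as.list(lambda)))
  terms$estimate <- beta
  terms$se <- NA_real_
  terms$p <- NA_real_
  out <- base
  out$coefficients <- terms
  out$lambda <- lambda
  out$merMod <- NULL
  class(out) <- c("ridge_fit", "lmm_fit")
  out
}
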