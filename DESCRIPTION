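Package: cogtraj
Title: Individualized Prediction of Cognitive Decline in Amyloid-Positive
    MCI and Mild Dementia
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Longitudinal random-intercept/slope linear mixed models for
    Mini-Mental State Examination (MMSE, 0-30) and Rey Auditory Verbal
    Learning Test (RAVLT, 0-75) trajectories in amyloid-positive mild
    cognitive impairment and mild dementia.  Provides a synthetic cohort
    simulator with annual visits, dropout and covariate missingness;
    multiple imputation by chained equations with predictive-mean
    matching and Rubin's-rules pooling; backward selection stabilised
    across imputed data sets; grouped ridge shrinkage; subject-level
    k-fold cross-validation (out-of-sample RMSE, MAD, R2); and a
    clinical prediction engine producing individualized trajectories,
    random-effect uncertainty bands, population percentile fans,
    time-to-threshold prognoses and hypothetical treatment-effect
    projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
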