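# shared fixtures, built in code

# small complete cohort (no covariate missingness)
quick_cohort <- function(n = 60, group = "MCI", seed = 1, ...) {
  simulate_cohort(cohort_config(group, n_subjects = n,
                                missing_rates = c(none = 0), seed = seed, ...))
}

# the two hypothetical patients used in the worked examples
fig3_mci_patient <- function(mmse_bl = 28, abeta = 925) {
  patient_profile("MCI", age = 66, sex = "male", mmse_bl = mmse_bl,
                  abeta = abeta, log_ptau = 3.415)
}
fig3_dementia_patient <- function(mmse_bl = 20, abeta = 625) {
  patient_profile("dementia", age = 66, sex = "female", mmse_bl = mmse_bl,
                  apoe4 = 2, abeta = abeta, log_ptau = 3.498)
}
fig2_mci_patient <- function() {
  patient_profile("MCI", age = 66, sex = "male", mmse_bl = 27,
                  abeta = 796.22, log_ptau = 3.415)
}

# term set of the generating MCI model (for fitting the true structure)
true_mci_terms <- function() {
  tab <- reference_coefs("MCI")
  df <- as.data.frame(tab)
  df[df$role != "intercept", c("term", "covariate", "transform", "role")]
}

# covariate specs collapsed to point masses (all SDs zero, degenerate
# categories) for degenerate-distribution checks
point_mass_params <- function(group = "MCI") {
  p <- covariate_defaults(group)
  for (nm in names(p)) {
    if (p[[nm]]$dist == "normal") p[[nm]]$sd <- 0
    if (p[[nm]]$dist == "lognormal") p[[nm]]$sdlog <- 0
    if (p[[nm]]$dist == "categorical")
      p[[nm]]$probs <- as.numeric(seq_along(p[[nm]]$levels) == 1)
  }
  p
}
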