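# Fixture builders used across the suite. All synthetic, built in code.

default_covariates <- function(weight = 70, height = 170, scr = 2.2,
                               age = 60, sex = "male", black = FALSE) {
  patient_covariates(age, sex, black, weight, height, scr)
}

# study sampled exactly from a bi-exponential truth, optional proportional
# lognormal noise (mean-1) under the current RNG state
make_biexp_study <- function(A = 150, alpha = 0.05, B = 50, beta = 0.005,
                             times = builtin_schedules()$ref_10h$times_min,
                             dose = 3235, cv = 0, patient_id = "P1",
                             study_index = 1, covariates = default_covariates()) {
  conc <- A * exp(-alpha * times) + B * exp(-beta * times)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    conc <- conc * stats::rlnorm(length(conc), -sdlog^2 / 2, sdlog)
  }
  clearance_study(patient_id, study_index, dose, times, conc,
                  covariates = covariates)
}

make_monoexp_study <- function(C0 = 200, k = 0.005,
                               times = builtin_schedules()$oc_8h$times_min,
                               dose = 3235, cv = 0, ...) {
  make_biexp_study(A = 0, alpha = 1, B = C0, beta = k, times = times,
                   dose = dose, cv = cv, ...)
}

# paired_gfr built from plain vectors with auto patient grouping
make_pairs <- function(ref, test, patients = NULL) {
  n <- length(ref)
  if (is.null(patients)) patients <- paste0("P", seq_len(n))
  idx <- stats::ave(seq_len(n), patients, FUN = seq_along)
  paired_gfr(patients, idx, ref, test)
}
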