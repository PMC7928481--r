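# Shared fixtures built in code.

STUDY_SCHEDULE <- c(0.25, 0.5, 1, 2, 4, 6, 8, 12)

# mono-exponential decline profile sampled on the study schedule
mono_profile <- function(c0 = 100, ke = 0.2, times = STUDY_SCHEDULE,
                         subject = "S1", analyte = "parent") {
  # LLOQ far below the curve so fixtures exercise the math, not censoring
  analyte_profile(subject, analyte, times, c0 * exp(-ke * times),
                  lloq_ng_ml = 1e-6)
}

# absorption + elimination profile (closed form) on a given schedule
bateman_profile <- function(c_scale = 500, ka = 8, ke = 0.24,
                            times = STUDY_SCHEDULE, subject = "S1",
                            analyte = "parent") {
  conc <- c_scale * ka / (ka - ke) * (exp(-ke * times) - exp(-ka * times))
  analyte_profile(subject, analyte, times, conc, lloq_ng_ml = 1e-6)
}

# write a concentration CSV from raw rows (for reader edge cases)
write_conc_rows <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("subject,analyte,time_h,conc_ng_ml,censored", rows), path)
  path
}

noiseless_params <- function(...) {
  sim_params(proportional_error_cv = 0, additive_error_sd_ng_ml = 0,
             between_subject_cv = 0, ...)
}

# numeric integral of t |-> f(t), tight tolerance, for oracle checks
quad <- function(f, lower, upper) {
  stats::integrate(f, lower, upper, rel.tol = 1e-10, subdivisions = 2000L)$value
}
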