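#' Reference PK indices from the koala subcutaneous tramadol study
#'
#' Per-subject non-compartmental indices for tramadol and its metabolites
#' M1 (O-desmethyltramadol) and M2 (N-desmethyltramadol) from a
#' single-dose s.c. study in six koalas: two at 2 mg/kg, four at 4 mg/kg,
#' sampled at 0.25-12 h. Tramadol rows carry AUC to infinity and AUMC;
#' metabolite rows carry the 0-12 h exposure only (their terminal phases
#' are too shallow within 12 h to extrapolate reliably). These indices are
#' the inputs for recomputing the derived parameters (Cl/F, Vz/F, MRT,
#' dose-normalized exposure), group summaries and metabolite:parent ratios.
#'
#' @return A tibble with columns `subject`, `group`, `analyte`,
#'   `t_half_h`, `tmax_h`, `cmax_ng_ml`, `auc_0_12`, `auc_0_inf`,
#'   `aumc_0_inf`.
#' @export
koala_reference_indices <- function() {
  readr::read_csv(system.file("extdata", "koala_tramadol_study_indices.csv",
                              package = "koalapk", mustWork = TRUE),
                  col_types = readr::cols(
                    subject = readr::col_character(),
                    group = readr::col_character(),
                    analyte = readr::col_character(),
                    .default = readr::col_double()),
                  progress = FALSE)
}

#' Reference dose events for the koala tramadol study
#'
#' Administered doses and body weights for the six study subjects. K1's
#' body weight is stored as dose/nominal-rate (18.2 mg / 2 mg/kg = 9.1 kg)
#' so that total dose, weight and the nominal per-kg rate are mutually
#' consistent; the other subjects' recorded weights already are.
#'
#' @return A list of [dose_event()] objects named by subject.
#' @export
koala_reference_doses <- function() {
  doses <- read_dose_csv(system.file("extdata", "koala_tramadol_study_doses.csv",
                                     package = "koalapk", mustWork = TRUE))
  stats::setNames(doses, vapply(doses, `[[`, character(1), "subject_id"))
}
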