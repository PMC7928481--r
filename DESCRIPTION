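Package: koalapk
Title: Non-Compartmental Pharmacokinetics of Tramadol and Its Metabolites
    from Sparse Plasma Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-compartmental pharmacokinetic (NCA) analysis of
    sparse concentration-time profiles, built around a study of subcutaneous
    tramadol in koalas. Provides a typed data model for concentration, dose,
    calibration and protein-binding tables with below-LLOQ censoring; an NCA
    engine (observed Cmax/Tmax, terminal rate-constant regression with
    automatic or explicit point selection, linear and linear-up/log-down
    trapezoidal AUC and AUMC, extrapolation to infinity, MRT, apparent
    clearance and volume of distribution, dose-normalized indices, group
    summaries); metabolite-to-parent exposure ratios, time-above-threshold
    efficacy prediction and dose-linearity ANOVA; bioanalytical calibration
    with 1/x weighting, quality-control acceptance and ultrafiltration
    plasma-protein-binding calculations; and a synthetic data generator with
    known ground truth (first-order subcutaneous absorption, one-compartment
    disposition, parent-to-metabolite cascade, assay error and LLOQ
    censoring) for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
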