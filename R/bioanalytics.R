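#' Fit an external-standard calibration line
#'
#' Weighted least-squares line of detector response on nominal
#' concentration. `weighting = "inverse_x"` uses weights proportional to
#' 1/nominal, the standard choice for heteroscedastic bioanalytical data
#' (assay error roughly proportional to concentration): it keeps the top of
#' the curve from dominating the fit and protects accuracy at the low end.
#' R-squared is computed on the weighted residuals; a curve with
#' r-squared <= 0.99 is flagged as failing the usual acceptance rule.
#'
#' @param nominal_ng_ml Nominal standard concentrations (>= 5 distinct
#'   levels), positive.
#' @param response Detector responses, positive, same length.
#' @param weighting `"inverse_x"` (default) or `"none"`.
#' @param analyte Analyte name carried in the result.
#' @return An object of class `calibration_curve`: list with `analyte`,
#'   `standards` (tibble), `slope`, `intercept`, `weighting`, `r_squared`,
#'   `range_ng_ml` (low, high), `acceptable` (r_squared > 0.99).
#' @examples
#' fit_calibration(c(15.62, 31.25, 62.5, 125, 250, 500),
#'                 2 * c(15.62, 31.25, 62.5, 125, 250, 500))
#' @export
fit_calibration <- function(nominal_ng_ml, response,
                            weighting = c("inverse_x", "none"),
                            analyte = "analyte") {
  weighting <- match.arg(weighting)
  if (length(nominal_ng_ml) != length(response))
    stop("nominal and response must have equal length", call. = FALSE)
  if (length(unique(nominal_ng_ml)) < 5)
    stop("calibration needs at least 5 distinct nominal levels", call. = FALSE)
  if (any(nominal_ng_ml <= 0) || any(response <= 0))
    stop("nominal concentrations and responses must be positive", call. = FALSE)
  w <- if (weighting == "inverse_x") 1 / nominal_ng_ml else rep(1, length(nominal_ng_ml))
  m <- stats::lm(response ~ nominal_ng_ml, weights = w)
  # weighted R^2 computed directly; summary.lm warns on exact-line standards
  wmean <- stats::weighted.mean(response, w)
  tss <- sum(w * (response - wmean)^2)
  r2 <- max(0, min(1, 1 - sum(w * stats::residuals(m)^2) / tss))
  structure(
    list(analyte = analyte,
         standards = tibble::tibble(nominal_ng_ml = nominal_ng_ml, response = response),
         slope = unname(stats::coef(m)[2]), intercept = unname(stats::coef(m)[1]),
         weighting = weighting, r_squared = r2,
         range_ng_ml = c(low = min(nominal_ng_ml), high = max(nominal_ng_ml)),
         acceptable = r2 > 0.99),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: response = %.4g + %.4g * conc (weighting %s)\n",
              x$analyte, x$intercept, x$slope, x$weighting))
  cat(sprintf("  range %g-%g ng/mL, r2 = %.5f%s\n", x$range_ng_ml[["low"]],
              x$range_ng_ml[["high"]], x$r_squared,
              if (!x$acceptable) "  [FLAG: r2 <= 0.99]" else ""))
  invisible(x)
}

#' Back-calculate concentration from a calibration curve
#'
#' Inverts the calibration line: (response - intercept)/slope. Results
#' outside the curve's calibrated range are returned but flagged, never
#' clamped.
#'
#' @param curve A [fit_calibration()] result.
#' @param response Detector response(s).
#' @return A tibble with `response`, `conc_ng_ml`, `in_range`.
#' @export
back_calculate <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("degenerate calibration curve: zero slope", call. = FALSE)
  conc <- (response - curve$intercept) / curve$slope
  tibble::tibble(response = response, conc_ng_ml = conc,
                 in_range = conc >= curve$range_ng_ml[["low"]] &
                   conc <= curve$range_ng_ml[["high"]])
}

#' Assess a quality-control level
#'
#' Accuracy = mean back-calculated concentration / nominal x 100; precision
#' = coefficient of variation (sample SD / mean x 100). The level passes
#' when precision is strictly below 15% and accuracy is within 20% of
#' nominal, i.e. in the closed interval \[80%, 120%\] — the conventional
#' bioanalytical acceptance rule, under which the lowest passing level
#' defines the LLOQ.
#'
#' @param back_calculated Numeric vector of >= 2 replicate back-calculated
#'   concentrations (ng/mL).
#' @param nominal_ng_ml Nominal concentration of the level.
#' @return An object of class `qc_result`: list with `nominal_ng_ml`, `n`,
#'   `mean`, `sd`, `accuracy_percent`, `precision_cv_percent`, `pass`.
#' @examples
#' qc_assess(c(15.0, 16.0, 15.9), 15.63)
#' @export
qc_assess <- function(back_calculated, nominal_ng_ml) {
  if (length(back_calculated) < 2)
    stop("qc_assess needs at least 2 replicates", call. = FALSE)
  m <- mean(back_calculated)
  s <- stats::sd(back_calculated)
  accuracy <- m / nominal_ng_ml * 100
  cv <- s / m * 100
  structure(
    list(nominal_ng_ml = nominal_ng_ml, n = length(back_calculated),
         mean = m, sd = s, accuracy_percent = accuracy,
         precision_cv_percent = cv,
         pass = (cv < 15) && (accuracy >= 80) && (accuracy <= 120)),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> nominal %g ng/mL (n=%d): accuracy %.1f%%, CV %.1f%% -> %s\n",
              x$nominal_ng_ml, x$n, x$accuracy_percent, x$precision_cv_percent,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Lowest passing QC level (LLOQ)
#'
#' @param qc_results A list of [qc_assess()] results.
#' @return The nominal concentration of the lowest passing level, or `NA`
#'   if none passes.
#' @export
lloq_from_qc <- function(qc_results) {
  passing <- vapply(qc_results, function(q) if (q$pass) q$nominal_ng_ml else NA_real_,
                    numeric(1))
  if (all(is.na(passing))) NA_real_ else min(passing, na.rm = TRUE)
}

#' Extraction recovery
#'
#' Mean extracted response as a percentage of the mean neat (unextracted)
#' response at the same nominal level.
#'
#' @param extracted_response Responses of extracted QC replicates.
#' @param neat_response Responses of neat standards at the same level.
#' @return Recovery in percent.
#' @export
recovery_percent <- function(extracted_response, neat_response) {
  if (mean(neat_response) <= 0) stop("neat responses must be positive", call. = FALSE)
  mean(extracted_response) / mean(neat_response) * 100
}

#' Percent bound to plasma proteins from an ultrafiltration pair
#'
#' Percent bound = 100 - (free/total x 100), from the total (pre-filter
#' plasma) and free (ultrafiltrate) concentrations of one measurement.
#' Non-specific binding of drug to the filtration membrane, measured in
#' protein-free buffer, is carried alongside for reporting but not
#' subtracted (appropriate when it is verified negligible, < 0.5%). A free
#' concentration exceeding total is physically impossible for a valid
#' assay; it yields a negative percent bound plus an attached finding, not
#' a silent clamp.
#'
#' @param total_ng_ml Total concentration(s) in plasma (positive).
#' @param free_ng_ml Free concentration(s) in the ultrafiltrate.
#' @param analyte Analyte name.
#' @param nonspecific_binding_percent Optional membrane binding, percent.
#' @return An object of class `binding_result`: list with `analyte`,
#'   `replicates` (tibble with per-replicate `percent_bound`), `mean`, `sd`,
#'   `nonspecific_binding_percent`, `findings` (character vector).
#' @examples
#' percent_bound(total_ng_ml = c(100, 102), free_ng_ml = c(25, 24.4), analyte = "M1")
#' @export
percent_bound <- function(total_ng_ml, free_ng_ml, analyte = "analyte",
                          nonspecific_binding_percent = NA_real_) {
  if (length(total_ng_ml) != length(free_ng_ml))
    stop("total and free must have equal length", call. = FALSE)
  if (any(!is.finite(total_ng_ml)) || any(total_ng_ml <= 0))
    stop("total concentrations must be positive", call. = FALSE)
  if (any(!is.finite(free_ng_ml)) || any(free_ng_ml < 0))
    stop("free concentrations must be non-negative", call. = FALSE)
  pb <- 100 - (free_ng_ml / total_ng_ml * 100)
  findings <- character(0)
  bad <- free_ng_ml > total_ng_ml
  if (any(bad))
    findings <- sprintf("replicate %d: free (%g) exceeds total (%g) ng/mL",
                        which(bad), free_ng_ml[bad], total_ng_ml[bad])
  structure(
    list(analyte = analyte,
         replicates = tibble::tibble(total_ng_ml = total_ng_ml,
                                     free_ng_ml = free_ng_ml,
                                     percent_bound = pb),
         mean = mean(pb), sd = if (length(pb) > 1) stats::sd(pb) else NA_real_,
         nonspecific_binding_percent = nonspecific_binding_percent,
         findings = findings),
    class = "binding_result"
  )
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("<binding_result> %s: %.2f%% bound (SD %.2f, n=%d)\n",
              x$analyte, x$mean, x$sd, nrow(x$replicates)))
  if (length(x$findings)) cat("  findings:", paste(x$findings, collapse = "; "), "\n")
  invisible(x)
}

#' Read a calibration/QC CSV
#'
#' Expected columns: `analyte,nominal_ng_ml,response,replicate`.
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    analyte = readr::col_character(), nominal_ng_ml = readr::col_double(),
    response = readr::col_double(), replicate = readr::col_character()),
    progress = FALSE)
  required <- c("analyte", "nominal_ng_ml", "response", "replicate")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("calibration CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw
}

#' Read a protein-binding CSV
#'
#' Expected columns: `analyte,fraction,conc_ng_ml,replicate` with fraction
#' one of `total`, `free`, `buffer` (buffer rows quantify non-specific
#' membrane binding).
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_binding_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    analyte = readr::col_character(), fraction = readr::col_character(),
    conc_ng_ml = readr::col_double(), replicate = readr::col_character()),
    progress = FALSE)
  required <- c("analyte", "fraction", "conc_ng_ml", "replicate")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("binding CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- !raw$fraction %in% c("total", "free", "buffer")
  if (any(bad))
    stop("fraction must be one of total/free/buffer; got: ",
         paste(unique(raw$fraction[bad]), collapse = ", "), call. = FALSE)
  raw
}

#' Summarize a binding table per analyte
#'
#' Pairs total/free rows by analyte and replicate, computes per-replicate
#' percent bound, and reports both pooled and (when replicate labels encode
#' a spiking level, e.g. `"500-1"`) per-level summaries.
#'
#' @param binding A tibble from [read_binding_csv()].
#' @return A list of [percent_bound()] results, one per analyte.
#' @export
binding_summary <- function(binding) {
  out <- list()
  for (a in unique(binding$analyte)) {
    part <- binding[binding$analyte == a & binding$fraction != "buffer", ]
    tot <- part[part$fraction == "total", ]
    fre <- part[part$fraction == "free", ]
    merged <- dplyr::inner_join(tot, fre, by = "replicate", suffix = c("_total", "_free"))
    unpaired <- setdiff(union(tot$replicate, fre$replicate), merged$replicate)
    if (length(unpaired) > 0)
      stop(sprintf("analyte '%s': missing paired total/free fraction for replicate(s) %s",
                   a, paste(unpaired, collapse = ", ")), call. = FALSE)
    buf <- binding[binding$analyte == a & binding$fraction == "buffer", ]
    nsb <- if (nrow(buf) > 0 && nrow(tot) > 0)
      100 - mean(buf$conc_ng_ml) / mean(tot$conc_ng_ml) * 100 else NA_real_
    out[[a]] <- percent_bound(merged$conc_ng_ml_total, merged$conc_ng_ml_free,
                              analyte = a, nonspecific_binding_percent = nsb)
  }
  out
}
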