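#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

BLQ_TOKEN <- "BLQ"

#' Construct a single-subject, single-analyte concentration-time profile
#'
#' An `analyte_profile` holds one ordered concentration-time series for one
#' subject and one analyte, together with the assay's lower limit of
#' quantification (LLOQ). Records flagged `censored` are below the LLOQ and
#' carry no usable numeric concentration; downstream NCA applies an explicit
#' imputation rule (zero before Tmax, excluded at/after Tmax) rather than
#' ever integrating a censored value.
#'
#' @param subject_id Subject identifier (character scalar).
#' @param analyte Analyte name, e.g. `"tramadol"`, `"M1"`, `"M2"`.
#' @param time_h Sampling times in hours post-dose, non-negative and strictly
#'   increasing.
#' @param conc_ng_ml Concentrations in ng/mL; `NA` where `censored` is `TRUE`.
#' @param censored Logical, `TRUE` for below-LLOQ records. Defaults to all
#'   `FALSE`.
#' @param lloq_ng_ml Lower limit of quantification in ng/mL (positive).
#' @return An object of class `analyte_profile`: a list with `subject_id`,
#'   `analyte`, `lloq_ng_ml` and a tibble `records`
#'   (`time_h`, `conc_ng_ml`, `censored`).
#' @examples
#' analyte_profile("K1", "tramadol",
#'   time_h = c(0.25, 0.5, 1, 2),
#'   conc_ng_ml = c(387.8, 310.2, 250.1, 160.3),
#'   lloq_ng_ml = 15.63
#' )
#' @export
analyte_profile <- function(subject_id, analyte, time_h, conc_ng_ml,
                            censored = rep(FALSE, length(time_h)),
                            lloq_ng_ml = 15.63) {
  stopifnot(length(subject_id) == 1L, length(analyte) == 1L,
            is.numeric(time_h), length(lloq_ng_ml) == 1L)
  if (!is.finite(lloq_ng_ml) || lloq_ng_ml <= 0)
    stop("lloq_ng_ml must be a positive number", call. = FALSE)
  n <- length(time_h)
  if (length(conc_ng_ml) != n || length(censored) != n)
    stop("time_h, conc_ng_ml and censored must have equal length", call. = FALSE)
  if (any(!is.finite(time_h)) || any(time_h < 0))
    stop("time_h must be finite and non-negative", call. = FALSE)
  if (is.unsorted(time_h, strictly = TRUE))
    stop(sprintf("times for subject '%s' analyte '%s' must be strictly increasing with no duplicates",
                 subject_id, analyte), call. = FALSE)
  censored <- as.logical(censored)
  if (anyNA(censored)) stop("censored must be TRUE/FALSE", call. = FALSE)
  conc_ng_ml <- as.numeric(conc_ng_ml)
  bad <- !censored & (!is.finite(conc_ng_ml) | conc_ng_ml < 0)
  if (any(bad))
    stop(sprintf("uncensored concentrations must be finite and non-negative (subject '%s', t = %s h)",
                 subject_id, paste(time_h[bad], collapse = ", ")), call. = FALSE)
  conc_ng_ml[censored] <- NA_real_
  structure(
    list(
      subject_id = as.character(subject_id),
      analyte = as.character(analyte),
      lloq_ng_ml = as.numeric(lloq_ng_ml),
      records = tibble(time_h = as.numeric(time_h),
                       conc_ng_ml = conc_ng_ml,
                       censored = censored)
    ),
    class = "analyte_profile"
  )
}

#' @export
print.analyte_profile <- function(x, ...) {
  cat(sprintf("<analyte_profile> subject %s, analyte %s, %d records, LLOQ %g ng/mL\n",
              x$subject_id, x$analyte, nrow(x$records), x$lloq_ng_ml))
  print(x$records, ...)
  invisible(x)
}

#' Construct a dose event
#'
#' One administered dose for one subject. Exactly one dosing event per
#' subject is supported (single s.c. bolus study design). When
#' `dose_mg_per_kg` is omitted it is computed as `dose_mg / body_weight_kg`;
#' when all three are supplied they must agree to within `tol` (default 1%,
#' accommodating table rounding).
#'
#' @param subject_id Subject identifier.
#' @param dose_mg Total administered dose in mg (positive).
#' @param body_weight_kg Body weight in kg (positive).
#' @param route Administration route: `"sc"`, `"iv"` or `"oral"`.
#' @param dose_mg_per_kg Optional nominal dose rate in mg/kg.
#' @param tol Relative tolerance for the dose consistency check.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(subject_id, dose_mg, body_weight_kg, route = c("sc", "iv", "oral"),
                       dose_mg_per_kg = NULL, tol = 0.01) {
  route <- match.arg(route)
  stopifnot(length(dose_mg) == 1L, length(body_weight_kg) == 1L)
  if (!is.finite(dose_mg) || dose_mg <= 0) stop("dose_mg must be positive", call. = FALSE)
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body_weight_kg must be positive", call. = FALSE)
  if (is.null(dose_mg_per_kg)) {
    dose_mg_per_kg <- dose_mg / body_weight_kg
  } else {
    if (!is.finite(dose_mg_per_kg) || dose_mg_per_kg <= 0)
      stop("dose_mg_per_kg must be positive", call. = FALSE)
    rel <- abs(dose_mg - dose_mg_per_kg * body_weight_kg) / dose_mg
    if (rel > tol)
      stop(sprintf("dose_mg (%g) and dose_mg_per_kg x body_weight_kg (%g) disagree by %.1f%% (> %.0f%%) for subject '%s'",
                   dose_mg, dose_mg_per_kg * body_weight_kg, 100 * rel, 100 * tol,
                   subject_id), call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), dose_mg = dose_mg,
         body_weight_kg = body_weight_kg, dose_mg_per_kg = dose_mg_per_kg,
         route = route),
    class = "dose_event"
  )
}

#' @export
print.dose_event <- function(x, ...) {
  cat(sprintf("<dose_event> subject %s: %g mg (%g mg/kg, %g kg), route %s\n",
              x$subject_id, x$dose_mg, x$dose_mg_per_kg, x$body_weight_kg, x$route))
  invisible(x)
}

#' Assemble a study dataset
#'
#' Bundles concentration profiles and dose events, with optional per-subject
#' group labels (e.g. dose level). Structural validation is deferred to
#' [validate_dataset()], which reports findings rather than failing, so that
#' partially inconsistent real-world tables can be inspected.
#'
#' @param profiles List of [analyte_profile()] objects.
#' @param doses List of [dose_event()] objects.
#' @param groups Optional named character vector mapping subject_id to a
#'   group label.
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(profiles, doses, groups = NULL) {
  stopifnot(all(vapply(profiles, inherits, logical(1), "analyte_profile")),
            all(vapply(doses, inherits, logical(1), "dose_event")))
  names(profiles) <- vapply(profiles, function(p) paste(p$subject_id, p$analyte, sep = "/"),
                            character(1))
  names(doses) <- vapply(doses, `[[`, character(1), "subject_id")
  if (anyDuplicated(names(doses)))
    stop("more than one dose event for subject(s): ",
         paste(unique(names(doses)[duplicated(names(doses))]), collapse = ", "),
         call. = FALSE)
  structure(list(profiles = profiles, doses = doses, groups = groups),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d profiles (%d subjects x %d analytes), %d dose events\n",
              length(x$profiles),
              length(unique(vapply(x$profiles, `[[`, character(1), "subject_id"))),
              length(unique(vapply(x$profiles, `[[`, character(1), "analyte"))),
              length(x$doses)))
  invisible(x)
}

#' Find the dose event for a subject
#' @param ds A `study_dataset`.
#' @param subject_id Subject identifier.
#' @return The matching [dose_event()], or an error if absent.
#' @export
dose_for <- function(ds, subject_id) {
  d <- ds$doses[[subject_id]]
  if (is.null(d)) stop(sprintf("no dose event for subject '%s'", subject_id), call. = FALSE)
  d
}

#' Read a long-format concentration CSV
#'
#' Expected columns: `subject,analyte,time_h,conc_ng_ml,censored`. Values
#' below the LLOQ are encoded as the literal token `"BLQ"` in `conc_ng_ml`
#' (with `censored` TRUE); the token is deliberately non-numeric so a
#' censored value can never be mistaken for a measured zero. Decimal hours,
#' decimal point (not comma), UTF-8.
#'
#' @param path Path to the CSV file.
#' @param lloq Lower limit of quantification applied to all profiles (ng/mL).
#' @return A list of [analyte_profile()] objects, one per subject x analyte,
#'   records sorted by time.
#' @seealso [write_concentration_csv()], [read_dose_csv()]
#' @export
read_concentration_csv <- function(path, lloq = 15.63) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("subject", "analyte", "time_h", "conc_ng_ml", "censored")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("concentration CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  time_h <- parse_strict_numeric(raw$time_h, path, "time_h")
  censored <- parse_censored(raw$censored, raw$conc_ng_ml)
  conc <- rep(NA_real_, nrow(raw))
  num_rows <- which(!censored)
  conc[num_rows] <- parse_strict_numeric(raw$conc_ng_ml[num_rows], path, "conc_ng_ml")

  df <- tibble(subject = raw$subject, analyte = raw$analyte,
               time_h = time_h, conc_ng_ml = conc, censored = censored)
  split_keys <- split(seq_len(nrow(df)), paste(df$subject, df$analyte, sep = "/"))
  profiles <- lapply(split_keys, function(idx) {
    part <- df[idx, ][order(df$time_h[idx]), ]
    if (anyDuplicated(part$time_h))
      stop(sprintf("duplicate time(s) %s h for subject '%s' analyte '%s' in %s",
                   paste(unique(part$time_h[duplicated(part$time_h)]), collapse = ", "),
                   part$subject[1], part$analyte[1], path), call. = FALSE)
    analyte_profile(part$subject[1], part$analyte[1], part$time_h,
                    part$conc_ng_ml, part$censored, lloq_ng_ml = lloq)
  })
  unname(profiles)
}

parse_strict_numeric <- function(x, path, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad) || anyNA(x))
    stop(sprintf("malformed numeric value(s) in column '%s' of %s: %s",
                 col, path, paste(utils::head(x[bad | is.na(x)], 5), collapse = ", ")),
         call. = FALSE)
  out
}

parse_censored <- function(censored_col, conc_col) {
  cen <- tolower(trimws(censored_col)) %in% c("true", "t", "1", "yes")
  blq <- toupper(trimws(conc_col)) == BLQ_TOKEN
  if (any(blq & !cen))
    stop("rows with conc_ng_ml = 'BLQ' must have censored = TRUE", call. = FALSE)
  if (any(cen & !blq))
    stop("censored rows must encode conc_ng_ml as the token 'BLQ'", call. = FALSE)
  cen
}

#' Read a dose CSV
#'
#' Expected columns: `subject,dose_mg,body_weight_kg,route`.
#'
#' @param path Path to the CSV file.
#' @return A list of [dose_event()] objects.
#' @export
read_dose_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("subject", "dose_mg", "body_weight_kg", "route")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("dose CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(raw)), function(i) {
    dose_event(raw$subject[i],
               parse_strict_numeric(raw$dose_mg[i], path, "dose_mg"),
               parse_strict_numeric(raw$body_weight_kg[i], path, "body_weight_kg"),
               route = raw$route[i])
  })
}

#' Write profiles to a concentration CSV
#'
#' Inverse of [read_concentration_csv()]: censored records are written as
#' the `"BLQ"` token, numeric values with enough digits that a write-read
#' round trip preserves anything representable with 6 significant digits.
#'
#' @param profiles A list of [analyte_profile()] objects or a `study_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentration_csv <- function(profiles, path) {
  if (inherits(profiles, "study_dataset")) profiles <- profiles$profiles
  rows <- dplyr::bind_rows(lapply(profiles, function(p) {
    tibble(subject = p$subject_id, analyte = p$analyte,
           time_h = fmt_num(p$records$time_h),
           conc_ng_ml = ifelse(p$records$censored, BLQ_TOKEN, fmt_num(p$records$conc_ng_ml)),
           censored = ifelse(p$records$censored, "TRUE", "FALSE"))
  }))
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' Write dose events to a dose CSV
#' @param doses A list of [dose_event()] objects or a `study_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_csv <- function(doses, path) {
  if (inherits(doses, "study_dataset")) doses <- doses$doses
  rows <- dplyr::bind_rows(lapply(doses, function(d) {
    tibble(subject = d$subject_id, dose_mg = fmt_num(d$dose_mg),
           body_weight_kg = fmt_num(d$body_weight_kg), route = d$route)
  }))
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Validate a study dataset
#'
#' Checks the structural invariants that the constructors cannot enforce
#' across objects: every profile's subject has exactly one dose event, no
#' dose event is orphaned, and no uncensored concentration sits below the
#' profile's LLOQ. Reports rather than fails; an empty result means the
#' dataset is clean.
#'
#' @param ds A [study_dataset()].
#' @return A tibble of findings with columns `subject`, `analyte`, `time_h`
#'   and `message`; zero rows when all invariants hold.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  findings <- list()
  add <- function(subject, analyte, time_h, message) {
    findings[[length(findings) + 1L]] <<- tibble(
      subject = subject, analyte = analyte, time_h = time_h, message = message)
  }
  profile_subjects <- unique(vapply(ds$profiles, `[[`, character(1), "subject_id"))
  dose_subjects <- vapply(ds$doses, `[[`, character(1), "subject_id")
  for (s in setdiff(profile_subjects, dose_subjects))
    add(s, NA_character_, NA_real_, "no dose event for subject")
  for (s in setdiff(dose_subjects, profile_subjects))
    add(s, NA_character_, NA_real_, "dose event for unknown subject (no profiles)")
  for (p in ds$profiles) {
    low <- !p$records$censored & p$records$conc_ng_ml < p$lloq_ng_ml &
      p$records$conc_ng_ml > 0
    for (t in p$records$time_h[low])
      add(p$subject_id, p$analyte, t,
          sprintf("uncensored concentration below LLOQ (%g ng/mL)", p$lloq_ng_ml))
  }
  if (length(findings) == 0)
    return(tibble(subject = character(), analyte = character(),
                  time_h = numeric(), message = character()))
  dplyr::bind_rows(findings)
}
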