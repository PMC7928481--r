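#' Usable concentration-time points for integration
#'
#' Applies the below-LLOQ (BLQ) handling rule: censored records before Tmax
#' are imputed as 0 (drug not yet quantifiable during absorption), censored
#' records at or after Tmax are excluded (unknown, not zero, during
#' elimination). Tmax is the time of the maximum uncensored concentration.
#'
#' @param profile An [analyte_profile()].
#' @return A tibble with columns `time_h`, `conc_ng_ml` (censored handled),
#'   ordered by time.
#' @keywords internal
nca_points <- function(profile) {
  stopifnot(inherits(profile, "analyte_profile"))
  rec <- profile$records
  if (all(rec$censored)) stop("profile has no uncensored records", call. = FALSE)
  tmax <- rec$time_h[!rec$censored][which.max(rec$conc_ng_ml[!rec$censored])]
  pre <- rec$censored & rec$time_h < tmax
  keep <- !rec$censored | pre
  conc <- rec$conc_ng_ml
  conc[pre] <- 0
  tibble::tibble(time_h = rec$time_h[keep], conc_ng_ml = conc[keep])
}

#' Observed peak concentration and its time
#'
#' Cmax and Tmax are read directly from the measured (uncensored)
#' concentrations, with ties broken by the earliest time.
#'
#' @param profile An [analyte_profile()].
#' @return A list with `cmax_ng_ml` and `tmax_h`.
#' @export
observed_peak <- function(profile) {
  stopifnot(inherits(profile, "analyte_profile"))
  rec <- profile$records[!profile$records$censored, ]
  if (nrow(rec) == 0)
    stop(sprintf("no uncensored records for subject '%s' analyte '%s': peak undefined",
                 profile$subject_id, profile$analyte), call. = FALSE)
  i <- which.max(rec$conc_ng_ml)  # which.max returns the first maximum
  list(cmax_ng_ml = rec$conc_ng_ml[i], tmax_h = rec$time_h[i])
}

#' Fit the terminal elimination phase
#'
#' Ordinary least squares of log concentration on time over a suffix of the
#' post-Tmax samples. The terminal rate constant kel is the negative slope
#' and t1/2 = ln2/kel. When `point_times` is not given, every suffix window
#' of at least `min_points` points strictly after Tmax is fitted and the one
#' maximizing adjusted R-squared is selected, ties (within 1e-9) going to
#' the window with more points. An explicit `point_times` overrides the
#' automatic selection and may have as few as 2 points, for reproducing a
#' hand-picked published fit.
#'
#' @param profile An [analyte_profile()].
#' @param point_times Optional numeric vector of observed times to use.
#' @param min_points Minimum window size for automatic selection (default 3).
#' @return An object of class `terminal_fit`: a list with `kel_per_h`,
#'   `t_half_h`, `n_points`, `r_squared`, `adj_r_squared`, `point_times`,
#'   `log_intercept`.
#' @export
fit_terminal <- function(profile, point_times = NULL, min_points = 3L) {
  pts <- nca_points(profile)
  pts <- pts[pts$conc_ng_ml > 0, ]
  peak <- observed_peak(profile)

  if (!is.null(point_times)) {
    missing_t <- setdiff(point_times, profile$records$time_h)
    if (length(missing_t) > 0)
      stop(sprintf("terminal point time(s) %s h not observed for subject '%s' analyte '%s'",
                   paste(missing_t, collapse = ", "), profile$subject_id, profile$analyte),
           call. = FALSE)
    sel <- pts[pts$time_h %in% point_times, ]
    if (nrow(sel) < 2)
      stop("terminal fit needs at least 2 usable (positive, uncensored) points",
           call. = FALSE)
    fit <- loglinear_fit(sel$time_h, sel$conc_ng_ml)
    if (fit$slope >= 0)
      stop("no terminal phase: selected points have non-negative log-linear slope",
           call. = FALSE)
    return(new_terminal_fit(fit, sel$time_h))
  }

  cand <- pts[pts$time_h > peak$tmax_h, ]
  if (nrow(cand) < min_points)
    stop(sprintf("insufficient data: %d usable point(s) after Tmax, need >= %d",
                 nrow(cand), min_points), call. = FALSE)
  best <- NULL
  for (start in seq_len(nrow(cand) - min_points + 1L)) {
    sel <- cand[start:nrow(cand), ]
    fit <- loglinear_fit(sel$time_h, sel$conc_ng_ml)
    if (fit$slope >= 0) next
    if (is.null(best) || fit$adj_r_squared > best$fit$adj_r_squared + 1e-9 ||
        (abs(fit$adj_r_squared - best$fit$adj_r_squared) <= 1e-9 &&
         nrow(sel) > length(best$times))) {
      best <- list(fit = fit, times = sel$time_h)
    }
  }
  if (is.null(best))
    stop("no terminal phase: every candidate window has a non-negative slope",
         call. = FALSE)
  new_terminal_fit(best$fit, best$times)
}

loglinear_fit <- function(time_h, conc) {
  y <- log(conc)
  m <- stats::lm(y ~ time_h)
  n <- length(time_h)
  tss <- sum((y - mean(y))^2)
  # R^2 computed directly: summary.lm warns on numerically perfect fits,
  # which noiseless synthetic profiles produce routinely
  r2 <- if (tss > 0) max(0, 1 - sum(stats::residuals(m)^2) / tss) else 0
  adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  list(slope = unname(stats::coef(m)[2]), intercept = unname(stats::coef(m)[1]),
       r_squared = r2, adj_r_squared = adj)
}

new_terminal_fit <- function(fit, times) {
  kel <- -fit$slope
  structure(
    list(kel_per_h = kel, t_half_h = log(2) / kel, n_points = length(times),
         r_squared = fit$r_squared, adj_r_squared = fit$adj_r_squared,
         point_times = times, log_intercept = fit$intercept),
    class = "terminal_fit"
  )
}

#' @export
print.terminal_fit <- function(x, ...) {
  cat(sprintf("<terminal_fit> kel = %.4g /h, t1/2 = %.4g h (%d points: %s h, R2 = %.4f)\n",
              x$kel_per_h, x$t_half_h, x$n_points,
              paste(x$point_times, collapse = ", "), x$r_squared))
  invisible(x)
}

trapezoid_intervals <- function(time_h, conc, method, moment = c("exponential", "linear")) {
  moment <- match.arg(moment)
  n <- length(time_h)
  auc <- aumc <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    t1 <- time_h[i]; t2 <- time_h[i + 1L]
    c1 <- conc[i]; c2 <- conc[i + 1L]
    dt <- t2 - t1
    logdown <- method == "linear-up-log-down" && c2 < c1 && c1 > 0 && c2 > 0
    if (logdown) {
      k <- log(c1 / c2) / dt
      auc[i] <- (c1 - c2) / k
      aumc[i] <- if (moment == "exponential")
        (c1 * t1 - c2 * t2) / k + (c1 - c2) / k^2
      else dt * (t1 * c1 + t2 * c2) / 2
    } else {
      auc[i] <- dt * (c1 + c2) / 2
      aumc[i] <- dt * (t1 * c1 + t2 * c2) / 2
    }
  }
  list(auc = sum(auc), aumc = sum(aumc))
}

#' Area under the concentration-time curve to the last measurable point
#'
#' Computes AUC(0 - tlast) by the trapezoidal rule. With the default
#' `"linear-up-log-down"` method, rising or flat intervals (or intervals
#' touching zero) use the arithmetic trapezoid (C1+C2)/2 * dt, and strictly
#' falling intervals with both concentrations positive use the log
#' trapezoid (C1-C2) * dt / ln(C1/C2), which is exact when concentrations
#' decline mono-exponentially between samples. `"linear"` applies the
#' arithmetic trapezoid throughout. Integration starts at the first usable
#' sample (the origin is included only if a t = 0 record exists).
#'
#' @param profile An [analyte_profile()].
#' @param method `"linear-up-log-down"` (default) or `"linear"`.
#' @return AUC(0 - tlast) in ng*h/mL.
#' @export
auc_trapezoid <- function(profile, method = c("linear-up-log-down", "linear")) {
  method <- match.arg(method)
  pts <- nca_points(profile)
  if (nrow(pts) < 2) stop("AUC needs at least 2 usable points", call. = FALSE)
  trapezoid_intervals(pts$time_h, pts$conc_ng_ml, method)$auc
}

#' Area under the first-moment curve to the last measurable point
#'
#' AUMC(0 - tlast) = integral of t * C(t). Interval classification follows
#' the same rule as [auc_trapezoid()]; on log-down intervals the default
#' moment rule integrates t * C under the exponential interpolant in closed
#' form, for consistency with the log AUC increment. `moment = "linear"`
#' selects the plain linear trapezoid of t * C on those intervals instead.
#'
#' @inheritParams auc_trapezoid
#' @param moment Moment rule on log-down intervals: `"exponential"` or
#'   `"linear"`.
#' @return AUMC(0 - tlast) in ng*h^2/mL.
#' @export
aumc_trapezoid <- function(profile, method = c("linear-up-log-down", "linear"),
                           moment = c("exponential", "linear")) {
  method <- match.arg(method)
  moment <- match.arg(moment)
  pts <- nca_points(profile)
  if (nrow(pts) < 2) stop("AUMC needs at least 2 usable points", call. = FALSE)
  trapezoid_intervals(pts$time_h, pts$conc_ng_ml, method, moment)$aumc
}

#' Extrapolate AUC and AUMC to infinite time
#'
#' Adds the terminal-phase tail under mono-exponential decline at rate kel:
#' AUC tail = Clast/kel; AUMC tail = Clast*tlast/kel + Clast/kel^2.
#'
#' @param auc_0_tlast AUC to the last measurable concentration (ng*h/mL).
#' @param aumc_0_tlast AUMC to the last measurable concentration (ng*h^2/mL).
#' @param clast Last measurable concentration (ng/mL).
#' @param tlast Time of the last measurable concentration (h).
#' @param kel Terminal rate constant (1/h), positive.
#' @return A list with `auc_0_inf` and `aumc_0_inf`.
#' @export
extrapolate_to_infinity <- function(auc_0_tlast, aumc_0_tlast, clast, tlast, kel) {
  if (!is.finite(kel) || kel <= 0) stop("kel must be positive", call. = FALSE)
  if (clast < 0) stop("clast must be non-negative", call. = FALSE)
  list(auc_0_inf = auc_0_tlast + clast / kel,
       aumc_0_inf = aumc_0_tlast + clast * tlast / kel + clast / kel^2)
}

#' Derive secondary NCA indices from exposure, dose and kel
#'
#' MRT = AUMC(0-inf)/AUC(0-inf); apparent clearance Cl/F = dose/AUC(0-inf)
#' scaled per kg (mg/kg dose, ng*h/mL AUC -> L/kg/h, also reported in
#' mL/min/kg); apparent volume Vz/F = (Cl/F)/kel. Dose-normalized Cmax and
#' AUC divide by the total administered dose in mg. F, the bioavailability
#' of the extravascular route, is unknown without an i.v. arm, so clearance
#' and volume are apparent quantities.
#'
#' @param auc_0_inf AUC extrapolated to infinity (ng*h/mL), positive.
#' @param aumc_0_inf AUMC extrapolated to infinity (ng*h^2/mL), positive.
#' @param dose A [dose_event()].
#' @param kel Terminal rate constant (1/h), positive.
#' @param cmax Optional observed Cmax (ng/mL) for dose normalization.
#' @param auc_0_tlast Optional AUC(0-tlast) for dose normalization.
#' @return A list with `mrt_h`, `cl_over_f_l_kg_h`, `cl_over_f_ml_min_kg`,
#'   `vz_over_f_l_kg`, and (when inputs given) `cmax_per_dose`,
#'   `auc_inf_per_dose`, `auc_tlast_per_dose`.
#' @export
derive_indices <- function(auc_0_inf, aumc_0_inf, dose, kel,
                           cmax = NULL, auc_0_tlast = NULL) {
  stopifnot(inherits(dose, "dose_event"))
  if (!is.finite(auc_0_inf) || auc_0_inf <= 0) stop("AUC(0-inf) must be positive", call. = FALSE)
  if (!is.finite(kel) || kel <= 0) stop("kel must be positive", call. = FALSE)
  # mg/kg -> ng/kg (1e6), over ng*h/mL -> mL/kg/h, over 1e3 -> L/kg/h
  cl_l_kg_h <- dose$dose_mg_per_kg * 1e6 / auc_0_inf / 1e3
  out <- list(
    mrt_h = aumc_0_inf / auc_0_inf,
    cl_over_f_l_kg_h = cl_l_kg_h,
    cl_over_f_ml_min_kg = cl_l_kg_h * 1000 / 60,
    vz_over_f_l_kg = cl_l_kg_h / kel
  )
  if (!is.null(cmax)) out$cmax_per_dose <- cmax / dose$dose_mg
  if (!is.null(auc_0_inf)) out$auc_inf_per_dose <- auc_0_inf / dose$dose_mg
  if (!is.null(auc_0_tlast)) out$auc_tlast_per_dose <- auc_0_tlast / dose$dose_mg
  out
}

#' Full non-compartmental analysis of one profile
#'
#' Runs the complete NCA chain: observed peak, terminal-phase regression,
#' trapezoidal AUC/AUMC to tlast, extrapolation to infinity, and the derived
#' indices (MRT, Cl/F, Vz/F, dose-normalized exposure).
#'
#' @param profile An [analyte_profile()].
#' @param dose The subject's [dose_event()].
#' @param method Trapezoid method, see [auc_trapezoid()].
#' @param terminal_points Optional explicit terminal times, see
#'   [fit_terminal()].
#' @param min_points Minimum automatic terminal window size.
#' @param allow_missing_terminal When `TRUE`, a profile without an
#'   identifiable terminal phase (e.g. a slowly eliminated metabolite still
#'   near its peak at the last sample) yields a partial result — observed
#'   peak, Clast/tlast and AUC/AUMC to tlast, with kel, t1/2 and every
#'   extrapolated index `NA` — instead of an error. Default `FALSE`.
#' @return An object of class `nca_result`: a list with all indices
#'   (`cmax_ng_ml`, `tmax_h`, `clast_ng_ml`, `tlast_h`, `auc_0_tlast`,
#'   `auc_0_inf`, `aumc_0_tlast`, `aumc_0_inf`, `kel_per_h`, `t_half_h`,
#'   `mrt_h`, `cl_over_f_l_kg_h`, `cl_over_f_ml_min_kg`, `vz_over_f_l_kg`,
#'   `cmax_per_dose`, `auc_inf_per_dose`, `auc_tlast_per_dose`) plus the
#'   `terminal` fit object and identifiers.
#' @examples
#' p <- analyte_profile("K1", "tramadol", c(0.25, 0.5, 1, 2, 4, 6, 8, 12),
#'                      400 * exp(-0.3 * c(0.25, 0.5, 1, 2, 4, 6, 8, 12)))
#' d <- dose_event("K1", 18, 9, "sc")
#' nca(p, d)
#' @export
nca <- function(profile, dose, method = c("linear-up-log-down", "linear"),
                terminal_points = NULL, min_points = 3L,
                allow_missing_terminal = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "analyte_profile"), inherits(dose, "dose_event"))
  if (profile$subject_id != dose$subject_id)
    stop(sprintf("profile subject '%s' does not match dose subject '%s'",
                 profile$subject_id, dose$subject_id), call. = FALSE)
  peak <- observed_peak(profile)
  term <- if (allow_missing_terminal)
    tryCatch(fit_terminal(profile, point_times = terminal_points,
                          min_points = min_points),
             error = function(e) NULL)
  else fit_terminal(profile, point_times = terminal_points, min_points = min_points)
  pts <- nca_points(profile)
  pos <- pts[pts$conc_ng_ml > 0, ]
  clast <- pos$conc_ng_ml[nrow(pos)]
  tlast <- pos$time_h[nrow(pos)]
  auc_t <- auc_trapezoid(profile, method)
  aumc_t <- aumc_trapezoid(profile, method)
  if (!is.null(term)) {
    inf <- extrapolate_to_infinity(auc_t, aumc_t, clast, tlast, term$kel_per_h)
    idx <- derive_indices(inf$auc_0_inf, inf$aumc_0_inf, dose, term$kel_per_h,
                          cmax = peak$cmax_ng_ml, auc_0_tlast = auc_t)
    kel <- term$kel_per_h; t_half <- term$t_half_h
  } else {
    inf <- list(auc_0_inf = NA_real_, aumc_0_inf = NA_real_)
    idx <- list(mrt_h = NA_real_, cl_over_f_l_kg_h = NA_real_,
                cl_over_f_ml_min_kg = NA_real_, vz_over_f_l_kg = NA_real_,
                cmax_per_dose = peak$cmax_ng_ml / dose$dose_mg,
                auc_inf_per_dose = NA_real_,
                auc_tlast_per_dose = auc_t / dose$dose_mg)
    kel <- NA_real_; t_half <- NA_real_
  }
  structure(
    c(list(subject_id = profile$subject_id, analyte = profile$analyte,
           cmax_ng_ml = peak$cmax_ng_ml, tmax_h = peak$tmax_h,
           clast_ng_ml = clast, tlast_h = tlast,
           auc_0_tlast = auc_t, aumc_0_tlast = aumc_t,
           auc_0_inf = inf$auc_0_inf, aumc_0_inf = inf$aumc_0_inf,
           kel_per_h = kel, t_half_h = t_half),
      idx,
      list(terminal = term, method = method)),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %s / %s\n", x$subject_id, x$analyte))
  cat(sprintf("  Cmax %.2f ng/mL at Tmax %.3g h; Clast %.2f ng/mL at %g h\n",
              x$cmax_ng_ml, x$tmax_h, x$clast_ng_ml, x$tlast_h))
  if (is.null(x$terminal))
    cat("  terminal phase not evaluable\n")
  else
    cat(sprintf("  kel %.4f /h, t1/2 %.2f h (%d terminal points)\n",
                x$kel_per_h, x$t_half_h, x$terminal$n_points))
  cat(sprintf("  AUC0-tlast %.2f, AUC0-inf %.2f ng*h/mL; AUMC0-inf %.2f ng*h^2/mL\n",
              x$auc_0_tlast, x$auc_0_inf, x$aumc_0_inf))
  cat(sprintf("  MRT %.2f h; Cl/F %.2f L/kg/h (%.2f mL/min/kg); Vz/F %.2f L/kg\n",
              x$mrt_h, x$cl_over_f_l_kg_h, x$cl_over_f_ml_min_kg, x$vz_over_f_l_kg))
  invisible(x)
}

#' Tabulate NCA results
#'
#' Flattens a list of [nca()] results to a tibble, one row per subject x
#' analyte, with columns named as in standard PK index tables.
#'
#' @param results A list of `nca_result` objects (or a single one).
#' @return A tibble.
#' @export
nca_table <- function(results) {
  if (inherits(results, "nca_result")) results <- list(results)
  dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(
      subject = r$subject_id, analyte = r$analyte,
      cmax_ng_ml = r$cmax_ng_ml, tmax_h = r$tmax_h,
      kel_per_h = r$kel_per_h, t_half_h = r$t_half_h,
      auc_0_tlast = r$auc_0_tlast, auc_0_inf = r$auc_0_inf,
      aumc_0_inf = r$aumc_0_inf, mrt_h = r$mrt_h,
      cl_over_f_l_kg_h = r$cl_over_f_l_kg_h,
      cl_over_f_ml_min_kg = r$cl_over_f_ml_min_kg,
      vz_over_f_l_kg = r$vz_over_f_l_kg,
      cmax_per_dose = r$cmax_per_dose,
      auc_inf_per_dose = r$auc_inf_per_dose,
      auc_tlast_per_dose = r$auc_tlast_per_dose,
      clast_ng_ml = r$clast_ng_ml, tlast_h = r$tlast_h,
      terminal_points = if (is.null(r$terminal)) NA_character_
                        else paste(r$terminal$point_times, collapse = ";"),
      terminal_r_squared = if (is.null(r$terminal)) NA_real_
                           else r$terminal$r_squared
    )
  }))
}

#' Group summary statistics for PK indices
#'
#' Median, mean, sample SD (n-1 denominator), min, max and n per index.
#' The median of an even-sized sample is the midpoint of the two central
#' order statistics; SD for a single value is reported as `NA`.
#'
#' @param x A tibble of per-subject indices (e.g. from [nca_table()]), or a
#'   plain numeric vector.
#' @param fields Character vector of numeric columns to summarize; defaults
#'   to all numeric columns when `x` is a tibble.
#' @return A tibble with columns `index`, `n`, `mean`, `sd`, `median`,
#'   `min`, `max`.
#' @export
summarize_group <- function(x, fields = NULL) {
  if (is.numeric(x)) {
    x <- tibble::tibble(value = x)
    fields <- "value"
  }
  stopifnot(is.data.frame(x))
  if (is.null(fields))
    fields <- names(x)[vapply(x, is.numeric, logical(1))]
  dplyr::bind_rows(lapply(fields, function(f) {
    v <- x[[f]]
    if (is.null(v)) stop("unknown field: ", f, call. = FALSE)
    v <- v[!is.na(v)]
    if (length(v) < 1)  # e.g. an index not evaluable for any group member
      return(tibble::tibble(index = f, n = 0L, mean = NA_real_, sd = NA_real_,
                            median = NA_real_, min = NA_real_, max = NA_real_))
    tibble::tibble(index = f, n = length(v), mean = mean(v),
                   sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                   median = stats::median(v), min = min(v), max = max(v))
  }))
}
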