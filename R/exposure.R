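#' Minimally effective plasma concentrations used for efficacy prediction
#'
#' Named defaults, in ng/mL, taken from human analgesia literature:
#' 100 ng/mL for the parent drug (tramadol) and 36 ng/mL for the active
#' metabolite M1. Both are overridable wherever they are consumed.
#' @export
effective_thresholds <- c(tramadol = 100, M1 = 36)

#' Metabolite-to-parent exposure ratio
#'
#' The ratio of metabolite AUC to parent AUC over the same time window, a
#' standard marker of metabolic conversion (and, for an active metabolite,
#' of expected analgesic contribution). Both AUCs must refer to the same
#' window; the window label is propagated so mismatched windows cannot be
#' silently divided.
#'
#' @param met_auc Metabolite AUC (ng*h/mL), positive.
#' @param parent_auc Parent AUC (ng*h/mL), positive.
#' @param window Window label for `met_auc` (e.g. `"0-12h"`, `"0-inf"`).
#' @param parent_window Window label for `parent_auc`; must equal `window`.
#' @return An object of class `ratio_result`: list with `metabolite_auc`,
#'   `parent_auc`, `ratio`, `auc_window`.
#' @examples
#' metabolite_parent_ratio(840.99, 1669.29, window = "0-12h")
#' @export
metabolite_parent_ratio <- function(met_auc, parent_auc, window = "0-tlast",
                                    parent_window = window) {
  if (!identical(window, parent_window))
    stop(sprintf("AUC windows differ ('%s' vs '%s'): ratio undefined",
                 window, parent_window), call. = FALSE)
  if (!is.finite(met_auc) || met_auc <= 0 || !is.finite(parent_auc) || parent_auc <= 0)
    stop("both AUCs must be positive", call. = FALSE)
  structure(list(metabolite_auc = met_auc, parent_auc = parent_auc,
                 ratio = met_auc / parent_auc, auc_window = window),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio_result> %g : %g = %.2f (AUC %s)\n",
              x$metabolite_auc, x$parent_auc, x$ratio, x$auc_window))
  invisible(x)
}

#' Time above an efficacy threshold
#'
#' Total time, within the observed sampling window, that a concentration
#' profile spends at or above a threshold. Crossing times inside each
#' bracketing interval are located by interpolation: `"linear"` in
#' concentration, or `"log"` (linear in log concentration, i.e. exponential
#' between samples; falls back to linear on any interval with a
#' non-positive endpoint). No extrapolation beyond the first or last sample
#' is performed.
#'
#' @param profile An [analyte_profile()].
#' @param threshold_ng_ml Positive threshold concentration.
#' @param interpolation `"linear"` or `"log"`.
#' @return An object of class `threshold_exposure`: list with
#'   `threshold_ng_ml`, `time_above_h`, `first_crossing_h`,
#'   `last_crossing_h` (NA when the profile never crosses the threshold in
#'   the corresponding direction), `exceeded_at_all`.
#' @export
time_above_threshold <- function(profile, threshold_ng_ml,
                                 interpolation = c("linear", "log")) {
  interpolation <- match.arg(interpolation)
  if (!is.finite(threshold_ng_ml) || threshold_ng_ml <= 0)
    stop("threshold must be positive", call. = FALSE)
  pts <- nca_points(profile)
  if (nrow(pts) < 2) stop("need at least 2 usable points", call. = FALSE)
  t <- pts$time_h; c <- pts$conc_ng_ml
  above <- c >= threshold_ng_ml
  if (!any(above))
    return(structure(list(threshold_ng_ml = threshold_ng_ml, time_above_h = 0,
                          first_crossing_h = NA_real_, last_crossing_h = NA_real_,
                          exceeded_at_all = FALSE), class = "threshold_exposure"))
  cross_at <- function(i) {
    # crossing time within (t[i], t[i+1]); endpoints straddle the threshold
    c1 <- c[i]; c2 <- c[i + 1L]
    if (interpolation == "log" && c1 > 0 && c2 > 0) {
      t[i] + (t[i + 1L] - t[i]) * log(threshold_ng_ml / c1) / log(c2 / c1)
    } else {
      t[i] + (t[i + 1L] - t[i]) * (threshold_ng_ml - c1) / (c2 - c1)
    }
  }
  total <- 0
  first_up <- if (above[1]) NA_real_ else NULL
  last_down <- NULL
  seg_start <- if (above[1]) t[1] else NA_real_
  for (i in seq_len(length(t) - 1L)) {
    if (above[i] && above[i + 1L]) {
      # stays above
    } else if (above[i] && !above[i + 1L]) {
      tc <- cross_at(i)
      total <- total + (tc - seg_start)
      last_down <- tc
      seg_start <- NA_real_
    } else if (!above[i] && above[i + 1L]) {
      tc <- cross_at(i)
      seg_start <- tc
      if (is.null(first_up)) first_up <- tc
    }
  }
  if (!is.na(seg_start)) total <- total + (t[length(t)] - seg_start)
  structure(list(threshold_ng_ml = threshold_ng_ml, time_above_h = total,
                 first_crossing_h = if (is.null(first_up)) NA_real_ else first_up,
                 last_crossing_h = if (is.null(last_down)) NA_real_ else last_down,
                 exceeded_at_all = TRUE),
            class = "threshold_exposure")
}

#' @export
print.threshold_exposure <- function(x, ...) {
  cat(sprintf("<threshold_exposure> %.4g h at/above %g ng/mL%s\n",
              x$time_above_h, x$threshold_ng_ml,
              if (!x$exceeded_at_all) " (never exceeded)" else ""))
  invisible(x)
}

#' One-way ANOVA on dose-normalized exposure indices
#'
#' Classical fixed-effects one-way analysis of variance comparing a
#' dose-normalized index (Cmax/dose or AUC/dose) across dose groups, the
#' standard dose-linearity screen: if kinetics are linear, normalizing by
#' dose removes the group effect and the test is non-significant. Fitted
#' through `stats::lm`/`stats::anova`.
#'
#' @param values Numeric vector of index values.
#' @param groups Group labels, same length as `values` (>= 2 distinct).
#' @param index Name of the index being tested (carried in the result).
#' @return An object of class `dose_linearity_test`: list with `index`,
#'   `f_statistic`, `df_between` (= groups - 1), `df_within` (= n - groups),
#'   `p_value`, `group_means`, `n`.
#' @examples
#' dose_normalized_anova(c(21.31, 36.77, 22.40, 27.55, 28.23, 24.30),
#'                       c("2mgkg", "2mgkg", "4mgkg", "4mgkg", "4mgkg", "4mgkg"),
#'                       index = "cmax_per_dose")
#' @export
dose_normalized_anova <- function(values, groups, index = "index") {
  if (length(values) != length(groups))
    stop("values and groups must have the same length", call. = FALSE)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 1)) stop("every group needs at least one value", call. = FALSE)
  a <- stats::anova(stats::lm(values ~ g))
  structure(
    list(index = index,
         f_statistic = a$`F value`[1],
         df_between = a$Df[1], df_within = a$Df[2],
         p_value = a$`Pr(>F)`[1],
         group_means = tapply(values, g, mean),
         n = length(values)),
    class = "dose_linearity_test"
  )
}

#' @export
print.dose_linearity_test <- function(x, ...) {
  cat(sprintf("<dose_linearity_test> %s: F(%d, %d) = %.3f, p = %.3f\n",
              x$index, x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}
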