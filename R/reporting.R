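#' Default analysis configuration
#'
#' @param method Trapezoid method, see [auc_trapezoid()].
#' @param terminal Terminal-phase selection: `"auto"`, or a named list
#'   mapping `"subject/analyte"` to explicit point times.
#' @param thresholds Named vector of efficacy thresholds in ng/mL, applied
#'   to profiles whose analyte name matches (the name `"parent"` is treated
#'   as an alias of `"tramadol"` and vice versa).
#' @param lloq LLOQ applied when reading concentration CSVs (ng/mL).
#' @param parent_analyte Analyte treated as the parent drug for ratios.
#' @param digits Rounding used in rendered report tables (raw CSV/JSON
#'   values are written unrounded).
#' @return A list of class `analysis_config`.
#' @export
default_config <- function(method = "linear-up-log-down", terminal = "auto",
                           thresholds = effective_thresholds, lloq = 15.63,
                           parent_analyte = "parent", digits = 2) {
  structure(list(method = method, terminal = terminal, thresholds = thresholds,
                 lloq = lloq, parent_analyte = parent_analyte, digits = digits),
            class = "analysis_config")
}

terminal_points_for <- function(config, subject, analyte) {
  if (identical(config$terminal, "auto")) return(NULL)
  config$terminal[[paste(subject, analyte, sep = "/")]]
}

threshold_for <- function(config, analyte, parent_analyte) {
  th <- config$thresholds
  if (analyte %in% names(th)) return(th[[analyte]])
  if (analyte == parent_analyte) {
    for (alias in c("parent", "tramadol"))
      if (alias %in% names(th)) return(th[[alias]])
  }
  NA_real_
}

#' Run the end-to-end NCA analysis and write report files
#'
#' Reads concentration and dose CSVs (see [read_concentration_csv()] and
#' [read_dose_csv()]), validates the dataset, runs [nca()] on every
#' subject x analyte profile, and assembles: a per-subject index table, a
#' per-group summary block (median, mean +/- SD, range), median-AUC
#' metabolite:parent ratios per group, time-above-threshold exposure for
#' every analyte with a configured threshold, and (when two or more dose
#' groups are present) dose-linearity ANOVA on Cmax/dose and AUC/dose.
#' Every terminal-phase point selection — the analysis's one subjective
#' step — is logged via `message()`.
#'
#' @param conc_csv Path to the concentration CSV.
#' @param dose_csv Path to the dose CSV.
#' @param out_dir Output directory; created if absent. Written files:
#'   `nca_individual.csv`, `nca_group_summary.csv`, `report.json`.
#' @param config An [default_config()] list.
#' @return Invisibly, a list with `individual` (tibble), `summary`
#'   (tibble), `ratios`, `thresholds`, `anova`, `findings` and `files`.
#' @export
run_nca_analysis <- function(conc_csv, dose_csv, out_dir,
                             config = default_config()) {
  profiles <- read_concentration_csv(conc_csv, lloq = config$lloq)
  doses <- read_dose_csv(dose_csv)
  ds <- study_dataset(profiles, doses)
  findings <- validate_dataset(ds)
  missing_dose <- grepl("no dose event", findings$message)
  if (any(missing_dose))
    stop("validation failed: ", paste(
      sprintf("%s (%s)", findings$message[missing_dose], findings$subject[missing_dose]),
      collapse = "; "), call. = FALSE)
  report <- assemble_report(ds, config)
  report$findings <- dplyr::bind_rows(findings, report$nca_failures)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  f_ind <- file.path(out_dir, "nca_individual.csv")
  f_sum <- file.path(out_dir, "nca_group_summary.csv")
  f_json <- file.path(out_dir, "report.json")
  readr::write_csv(report$individual, f_ind, progress = FALSE)
  readr::write_csv(report$summary, f_sum, progress = FALSE)
  jsonlite::write_json(
    list(individual = report$individual, summary = report$summary,
         ratios = report$ratios, thresholds = report$thresholds,
         anova = report$anova,
         findings = report$findings),
    f_json, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  report$files <- c(individual = f_ind, summary = f_sum, json = f_json)
  invisible(report)
}

assemble_report <- function(ds, config) {
  results <- list()
  failures <- list()
  for (p in ds$profiles) {
    tp <- terminal_points_for(config, p$subject_id, p$analyte)
    if (!is.null(tp)) {
      # explicit selections referencing unobserved times are configuration
      # errors and abort the run; data-driven failures below are findings
      missing_t <- setdiff(tp, p$records$time_h)
      if (length(missing_t) > 0)
        stop(sprintf("config: terminal point time(s) %s h not observed for subject '%s' analyte '%s'",
                     paste(missing_t, collapse = ", "), p$subject_id, p$analyte),
             call. = FALSE)
    }
    r <- tryCatch(nca(p, dose_for(ds, p$subject_id), method = config$method,
                      terminal_points = tp, allow_missing_terminal = TRUE),
                  error = function(e) e)
    if (inherits(r, "error")) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        subject = p$subject_id, analyte = p$analyte, time_h = NA_real_,
        message = paste("NCA not evaluable:", conditionMessage(r)))
      next
    }
    if (is.null(r$terminal)) {
      message(sprintf("terminal fit %s/%s: not evaluable (reported to tlast only)",
                      p$subject_id, p$analyte))
      failures[[length(failures) + 1L]] <- tibble::tibble(
        subject = p$subject_id, analyte = p$analyte, time_h = NA_real_,
        message = "terminal phase not evaluable: kel, t1/2 and extrapolated indices reported as NA")
    } else {
      message(sprintf("terminal fit %s/%s: points %s h (kel %.4g /h, R2 %.4f, %s)",
                      p$subject_id, p$analyte,
                      paste(r$terminal$point_times, collapse = ","),
                      r$kel_per_h, r$terminal$r_squared,
                      if (is.null(tp)) "auto" else "explicit"))
    }
    results[[length(results) + 1L]] <- r
  }
  if (length(results) == 0) stop("no profile could be analyzed", call. = FALSE)
  tab <- nca_table(results)
  group_of <- function(subject) {
    if (!is.null(ds$groups)) unname(ds$groups[subject])
    else sprintf("%gmgkg", vapply(subject, function(s) dose_for(ds, s)$dose_mg_per_kg,
                                  numeric(1)))
  }
  tab$group <- group_of(tab$subject)

  index_cols <- c("cmax_ng_ml", "tmax_h", "kel_per_h", "t_half_h", "auc_0_tlast",
                  "auc_0_inf", "aumc_0_inf", "mrt_h", "cl_over_f_l_kg_h",
                  "cl_over_f_ml_min_kg", "vz_over_f_l_kg", "cmax_per_dose",
                  "auc_inf_per_dose", "auc_tlast_per_dose")
  summary_tab <- tab |>
    dplyr::group_by(.data$analyte, .data$group) |>
    dplyr::group_modify(~ summarize_group(.x, fields = index_cols)) |>
    dplyr::ungroup()

  parent <- config$parent_analyte
  ratios <- list()
  if (parent %in% tab$analyte) {
    for (g in unique(tab$group)) {
      p_auc <- stats::median(tab$auc_0_tlast[tab$analyte == parent & tab$group == g])
      for (m in setdiff(unique(tab$analyte), parent)) {
        m_auc <- stats::median(tab$auc_0_tlast[tab$analyte == m & tab$group == g])
        rr <- metabolite_parent_ratio(m_auc, p_auc, window = "0-tlast")
        per_subj <- vapply(unique(tab$subject[tab$group == g]), function(s) {
          ms <- tab$auc_0_tlast[tab$subject == s & tab$analyte == m]
          ps <- tab$auc_0_tlast[tab$subject == s & tab$analyte == parent]
          if (length(ms) == 1 && length(ps) == 1) ms / ps else NA_real_
        }, numeric(1))
        ratios[[paste(m, g, sep = "_")]] <- list(
          metabolite = m, group = g, ratio_of_medians = rr$ratio,
          median_of_ratios = stats::median(per_subj, na.rm = TRUE),
          metabolite_median_auc = m_auc, parent_median_auc = p_auc,
          auc_window = rr$auc_window)
      }
    }
  }

  thresholds <- list()
  for (p in ds$profiles) {
    th <- threshold_for(config, p$analyte, parent)
    if (is.na(th)) next
    te <- time_above_threshold(p, th, interpolation = "linear")
    thresholds[[paste(p$subject_id, p$analyte, sep = "/")]] <- list(
      subject = p$subject_id, analyte = p$analyte, threshold_ng_ml = th,
      time_above_h = te$time_above_h, exceeded_at_all = te$exceeded_at_all)
  }

  anova_res <- list()
  if (length(unique(tab$group)) >= 2) {
    for (a in unique(tab$analyte)) {
      part <- tab[tab$analyte == a, ]
      for (idx in c("cmax_per_dose", "auc_tlast_per_dose")) {
        tst <- tryCatch(dose_normalized_anova(part[[idx]], part$group,
                                              index = paste(a, idx, sep = ".")),
                        error = function(e) NULL)
        if (is.null(tst)) next  # a group lost all its evaluable profiles
        anova_res[[paste(a, idx, sep = ".")]] <- list(
          index = tst$index, f_statistic = tst$f_statistic,
          df_between = tst$df_between, df_within = tst$df_within,
          p_value = tst$p_value)
      }
    }
  }

  list(individual = tab, summary = summary_tab, ratios = ratios,
       thresholds = thresholds, anova = anova_res,
       nca_failures = if (length(failures)) dplyr::bind_rows(failures) else NULL)
}

#' Run the plasma-protein-binding analysis and write a report
#'
#' Reads a binding CSV (see [read_binding_csv()]), pairs total/free
#' replicates per analyte, and writes per-replicate percent bound plus
#' mean +/- SD per analyte, with any free > total findings and the
#' non-specific (buffer) binding section.
#'
#' @param binding_csv Path to the binding CSV.
#' @param out_dir Output directory. Written files: `binding.csv`,
#'   `binding.json`.
#' @return Invisibly, a list with `results` (per-analyte
#'   [percent_bound()] objects), `table` (tibble) and `files`.
#' @export
run_binding_analysis <- function(binding_csv, out_dir) {
  binding <- read_binding_csv(binding_csv)
  results <- binding_summary(binding)
  tab <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(analyte = r$analyte, n = nrow(r$replicates),
                   mean_percent_bound = r$mean, sd_percent_bound = r$sd,
                   nonspecific_binding_percent = r$nonspecific_binding_percent,
                   findings = paste(r$findings, collapse = "; "))
  }))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  f_csv <- file.path(out_dir, "binding.csv")
  f_json <- file.path(out_dir, "binding.json")
  readr::write_csv(tab, f_csv, progress = FALSE)
  jsonlite::write_json(
    lapply(results, function(r)
      list(analyte = r$analyte, mean = r$mean, sd = r$sd,
           nonspecific_binding_percent = r$nonspecific_binding_percent,
           replicates = r$replicates, findings = r$findings)),
    f_json, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(results = results, table = tab,
                 files = c(csv = f_csv, json = f_json)))
}

#' Simulate a study and write its CSVs and ground-truth manifest
#'
#' Convenience wrapper over [simulate_study()] that emits the concentration
#' CSV, dose CSV and a JSON manifest of the realized per-subject parameters
#' and analytic indices.
#'
#' @param params A [sim_params()] object (see also [sim_preset()]).
#' @param out_dir Output directory.
#' @return Invisibly, the [simulate_study()] result with a `files` entry.
#' @export
write_simulated_study <- function(params, out_dir) {
  sim <- simulate_study(params)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  f_conc <- file.path(out_dir, "concentrations.csv")
  f_dose <- file.path(out_dir, "doses.csv")
  f_truth <- file.path(out_dir, "ground_truth.json")
  write_concentration_csv(sim$dataset, f_conc)
  write_dose_csv(sim$dataset, f_dose)
  jsonlite::write_json(
    list(params = unclass(sim$truth$params), subjects = sim$truth$subjects,
         indices = sim$truth$indices),
    f_truth, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  sim$files <- c(concentrations = f_conc, doses = f_dose, truth = f_truth)
  invisible(sim)
}

#' Concentration-time figure
#'
#' Optional ggplot2 export of the concentration-time profiles, on a linear
#' or semi-log concentration axis, with LLOQ and any efficacy thresholds
#' drawn as horizontal reference lines.
#'
#' @param profiles List of [analyte_profile()] objects or a
#'   [study_dataset()].
#' @param log_y Use a log10 concentration axis.
#' @param thresholds Named vector of reference concentrations (ng/mL).
#' @return A ggplot object.
#' @export
plot_concentration_time <- function(profiles, log_y = FALSE, thresholds = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_concentration_time requires ggplot2", call. = FALSE)
  if (inherits(profiles, "study_dataset")) profiles <- profiles$profiles
  df <- dplyr::bind_rows(lapply(profiles, function(p)
    tibble::tibble(subject = p$subject_id, analyte = p$analyte,
                   time_h = p$records$time_h, conc_ng_ml = p$records$conc_ng_ml,
                   censored = p$records$censored)))
  df <- df[!df$censored, ]
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$conc_ng_ml,
                                        colour = .data$subject)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/mL)")
  if (log_y) g <- g + ggplot2::scale_y_log10()
  if (!is.null(thresholds))
    g <- g + ggplot2::geom_hline(yintercept = unname(thresholds), linetype = "dashed")
  g
}
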