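#' Simulation parameters for a synthetic sparse-sampling PK study
#'
#' Defines the ground truth for the generator: a one-compartment disposition
#' model with first-order subcutaneous absorption for the parent drug and
#' first-order formation of named metabolites, evaluated on a sparse
#' clinical sampling schedule with multiplicative (proportional CV) plus
#' additive assay error and censoring below the LLOQ.
#'
#' `F_times_fa` is the product of bioavailability and fraction absorbed; it
#' is not identifiable from extravascular data alone and simply scales the
#' kinetics, so all apparent parameters recovered by NCA are `.../F`
#' quantities.
#'
#' @param n_subjects Number of subjects.
#' @param dose_mg_per_kg Dose rate (mg/kg).
#' @param body_weight_kg_range Two-element range; weights drawn uniformly.
#' @param F_times_fa Bioavailability x fraction absorbed, in (0, 1].
#' @param V_l_per_kg Apparent central volume (L/kg).
#' @param ka_per_h First-order absorption rate (1/h).
#' @param ke_per_h First-order parent elimination rate (1/h).
#' @param metabolites Named list; each element a list with `fm` (fraction of
#'   parent elimination forming the metabolite, in \[0,1\], summing to <= 1),
#'   `km_per_h` (metabolite elimination rate) and `Vm_l_per_kg` (apparent
#'   metabolite volume).
#' @param proportional_error_cv Proportional assay error CV (e.g. 0.10).
#' @param additive_error_sd_ng_ml Additive assay error SD (ng/mL).
#' @param lloq_ng_ml Lower limit of quantification (ng/mL).
#' @param schedule_h Sampling times (h), strictly increasing, positive.
#' @param between_subject_cv Lognormal between-subject CV applied to rates
#'   and volumes (ka, ke, V, km, Vm). Formation fractions are kept fixed so
#'   the sum-to-<=1 constraint always holds.
#' @param rng_seed Integer seed; mandatory for reproducible generation.
#' @return An object of class `sim_params`.
#' @seealso [sim_preset()] for ready-made parameter sets.
#' @export
sim_params <- function(n_subjects = 4,
                       dose_mg_per_kg = 4,
                       body_weight_kg_range = c(6.8, 9.0),
                       F_times_fa = 1,
                       V_l_per_kg = 8.6,
                       ka_per_h = 8,
                       ke_per_h = 0.24,
                       metabolites = list(
                         M1 = list(fm = 0.27, km_per_h = 0.028, Vm_l_per_kg = 8.6),
                         M2 = list(fm = 0.48, km_per_h = 0.094, Vm_l_per_kg = 8.6)),
                       proportional_error_cv = 0.10,
                       additive_error_sd_ng_ml = 15.63 / 3,
                       lloq_ng_ml = 15.63,
                       schedule_h = c(0.25, 0.5, 1, 2, 4, 6, 8, 12),
                       between_subject_cv = 0.30,
                       rng_seed = 1L) {
  check_pos <- function(x, nm) {
    if (any(!is.finite(x)) || any(x <= 0))
      stop(nm, " must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(n_subjects) || n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  check_pos(dose_mg_per_kg, "dose_mg_per_kg")
  check_pos(body_weight_kg_range, "body_weight_kg_range")
  if (length(body_weight_kg_range) != 2 || diff(body_weight_kg_range) < 0)
    stop("body_weight_kg_range must be c(low, high)", call. = FALSE)
  if (!is.finite(F_times_fa) || F_times_fa <= 0 || F_times_fa > 1)
    stop("F_times_fa must be in (0, 1]", call. = FALSE)
  check_pos(c(V_l_per_kg, ka_per_h, ke_per_h), "rates and volumes")
  if (length(metabolites) > 0) {
    if (is.null(names(metabolites)) || any(names(metabolites) == ""))
      stop("metabolites must be a named list", call. = FALSE)
    fms <- vapply(metabolites, `[[`, numeric(1), "fm")
    if (any(fms < 0) || any(fms > 1) || sum(fms) > 1)
      stop("metabolite formation fractions must lie in [0,1] and sum to <= 1",
           call. = FALSE)
    for (m in metabolites) check_pos(c(m$km_per_h, m$Vm_l_per_kg), "metabolite rates/volumes")
  }
  if (proportional_error_cv < 0 || additive_error_sd_ng_ml < 0)
    stop("error magnitudes must be non-negative", call. = FALSE)
  check_pos(lloq_ng_ml, "lloq_ng_ml")
  if (any(schedule_h <= 0) || is.unsorted(schedule_h, strictly = TRUE))
    stop("schedule_h must be positive and strictly increasing", call. = FALSE)
  if (between_subject_cv < 0) stop("between_subject_cv must be >= 0", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), dose_mg_per_kg = dose_mg_per_kg,
         body_weight_kg_range = body_weight_kg_range, F_times_fa = F_times_fa,
         V_l_per_kg = V_l_per_kg, ka_per_h = ka_per_h, ke_per_h = ke_per_h,
         metabolites = metabolites,
         proportional_error_cv = proportional_error_cv,
         additive_error_sd_ng_ml = additive_error_sd_ng_ml,
         lloq_ng_ml = lloq_ng_ml, schedule_h = schedule_h,
         between_subject_cv = between_subject_cv,
         rng_seed = as.integer(rng_seed)),
    class = "sim_params"
  )
}

#' Ready-made simulation presets
#'
#' * `"koala-4mgkg"`: the default parameter set — 4 subjects at 4 mg/kg
#'   s.c., parent ke 0.24 /h (t1/2 ~2.9 h), slow M1 elimination
#'   (km 0.028 /h, t1/2 ~24.8 h) and intermediate M2 (km 0.094 /h,
#'   t1/2 ~7.4 h), absorption ka 8 /h placing Tmax at ~0.45 h, LLOQ
#'   15.63 ng/mL on the 0.25-12 h schedule.
#' * `"koala-2mgkg"`: 2 subjects at 2 mg/kg, otherwise identical.
#' * `"fast-metabolizer"`: a single-subject preset with rapid parent
#'   elimination (ke 0.53 /h) and faster metabolite clearance, for
#'   exercising heterogeneous group summaries.
#' * `"flip-flop"`: absorption slower than elimination (ka 0.1 /h,
#'   ke 1 /h), so the observed terminal slope reflects the input process.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [sim_params()].
#' @return A `sim_params` object.
#' @export
sim_preset <- function(name = c("koala-4mgkg", "koala-2mgkg", "fast-metabolizer",
                                "flip-flop"), ...) {
  name <- match.arg(name)
  base <- switch(
    name,
    "koala-4mgkg" = list(),
    "koala-2mgkg" = list(n_subjects = 2, dose_mg_per_kg = 2),
    "fast-metabolizer" = list(
      n_subjects = 1, ke_per_h = 0.53,
      metabolites = list(
        M1 = list(fm = 0.27, km_per_h = 0.106, Vm_l_per_kg = 8.6),
        M2 = list(fm = 0.48, km_per_h = 0.159, Vm_l_per_kg = 8.6))),
    "flip-flop" = list(ka_per_h = 0.1, ke_per_h = 1, V_l_per_kg = 2)
  )
  do.call(sim_params, utils::modifyList(base, list(...)))
}

# mg/L -> ng/mL conversion factor for per-kg doses and volumes
MG_L_TO_NG_ML <- 1000

#' Parent drug concentration under first-order absorption
#'
#' One-compartment model with first-order input (single extravascular
#' bolus): C(t) = F*D*ka / (V*(ka-ke)) * (exp(-ke*t) - exp(-ka*t)), in
#' ng/mL with D in mg/kg and V in L/kg. At ka = ke the expression has the
#' continuous limit F*D*ka*t*exp(-ka*t)/V, used when the rates are within
#' ~1e-9 relative of each other.
#'
#' @param t Time(s) post-dose (h), non-negative.
#' @param params A [sim_params()] object (subject-level fields used:
#'   `dose_mg_per_kg`, `F_times_fa`, `V_l_per_kg`, `ka_per_h`, `ke_per_h`).
#' @return Concentration(s) in ng/mL; zero at t = 0.
#' @export
parent_concentration <- function(t, params) {
  stopifnot(inherits(params, "sim_params"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  ka <- params$ka_per_h; ke <- params$ke_per_h
  scale <- params$F_times_fa * params$dose_mg_per_kg / params$V_l_per_kg * MG_L_TO_NG_ML
  if (abs(ka - ke) < 1e-9 * max(ka, ke)) {
    scale * ka * t * exp(-ka * t)
  } else {
    scale * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
  }
}

#' Metabolite concentration in the absorption-parent-metabolite cascade
#'
#' Three-exponential catenary solution: depot -> parent (elimination ke, of
#' which a fraction fm forms the metabolite) -> metabolite (elimination
#' km). With km below ke the metabolite's apparent terminal half-life
#' exceeds the parent's (elimination-rate-limited kinetics); with formation
#' slower than elimination the terminal slope instead reflects formation
#' (flip-flop). Rates must be pairwise distinct (relative separation
#' > 1e-9) for the closed form.
#'
#' @param t Time(s) post-dose (h), non-negative.
#' @param params A [sim_params()] object.
#' @param metabolite Name of the metabolite (must exist in
#'   `params$metabolites`).
#' @return Concentration(s) in ng/mL; zero at t = 0.
#' @export
metabolite_concentration <- function(t, params, metabolite = "M1") {
  stopifnot(inherits(params, "sim_params"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  met <- params$metabolites[[metabolite]]
  if (is.null(met)) stop("unknown metabolite: ", metabolite, call. = FALSE)
  ka <- params$ka_per_h; ke <- params$ke_per_h; km <- met$km_per_h
  rates <- c(ka, ke, km)
  gaps <- abs(c(ka - ke, ka - km, ke - km))
  if (any(gaps < 1e-9 * max(rates)))
    stop("ka, ke and km must be pairwise distinct for the closed-form solution",
         call. = FALSE)
  amt <- params$F_times_fa * params$dose_mg_per_kg  # mg/kg absorbed
  coef <- met$fm * ke * ka * amt
  a_m <- coef * (exp(-ke * t) / ((ka - ke) * (km - ke)) +
                   exp(-ka * t) / ((ke - ka) * (km - ka)) +
                   exp(-km * t) / ((ke - km) * (ka - km)))
  a_m / met$Vm_l_per_kg * MG_L_TO_NG_ML
}

draw_lognormal <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

subject_params <- function(params, i, bw, bsv) {
  p <- params
  p$V_l_per_kg <- bsv$V[i]
  p$ka_per_h <- bsv$ka[i]
  p$ke_per_h <- bsv$ke[i]
  for (m in names(p$metabolites)) {
    p$metabolites[[m]]$km_per_h <- bsv$km[[m]][i]
    p$metabolites[[m]]$Vm_l_per_kg <- bsv$Vm[[m]][i]
  }
  p
}

#' Simulate a sparse-sampling PK study
#'
#' Draws per-subject kinetic parameters (lognormal between-subject
#' variability on rates and volumes), evaluates the closed-form parent and
#' metabolite concentrations on the sampling schedule, applies
#' multiplicative lognormal (proportional CV) and additive Gaussian assay
#' error, and censors values below the LLOQ as BLQ. The same seed always
#' reproduces the identical dataset.
#'
#' @param params A [sim_params()] object.
#' @return A list with `dataset` (a [study_dataset()]) and `truth`, a list
#'   holding per-subject realized parameters and the analytic `cmax`,
#'   `tmax` and `auc_0_inf` per analyte (tibble `truth$indices`), plus
#'   `truth$subjects`.
#' @examples
#' sim <- simulate_study(sim_preset("koala-4mgkg", rng_seed = 42))
#' sim$dataset
#' @export
simulate_study <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$rng_seed)
  n <- params$n_subjects
  bw <- stats::runif(n, params$body_weight_kg_range[1], params$body_weight_kg_range[2])
  cv <- params$between_subject_cv
  bsv <- list(
    V = draw_lognormal(n, params$V_l_per_kg, cv),
    ka = draw_lognormal(n, params$ka_per_h, cv),
    ke = draw_lognormal(n, params$ke_per_h, cv),
    km = lapply(params$metabolites, function(m) draw_lognormal(n, m$km_per_h, cv)),
    Vm = lapply(params$metabolites, function(m) draw_lognormal(n, m$Vm_l_per_kg, cv))
  )
  subjects <- sprintf("S%02d", seq_len(n))
  profiles <- list()
  doses <- list()
  truth_rows <- list()
  subj_param_rows <- list()
  for (i in seq_len(n)) {
    sp <- subject_params(params, i, bw, bsv)
    doses[[i]] <- dose_event(subjects[i],
                             dose_mg = sp$dose_mg_per_kg * bw[i],
                             body_weight_kg = bw[i], route = "sc")
    analytes <- c("parent", names(sp$metabolites))
    for (a in analytes) {
      clean <- if (a == "parent") parent_concentration(params$schedule_h, sp)
               else metabolite_concentration(params$schedule_h, sp, a)
      noisy <- apply_assay_error(clean, sp)
      cen <- noisy < sp$lloq_ng_ml
      profiles[[length(profiles) + 1L]] <-
        analyte_profile(subjects[i], a, params$schedule_h,
                        ifelse(cen, NA_real_, noisy), censored = cen,
                        lloq_ng_ml = sp$lloq_ng_ml)
      truth_rows[[length(truth_rows) + 1L]] <- analytic_indices(sp, a, subjects[i])
    }
    subj_param_rows[[i]] <- tibble::tibble(
      subject = subjects[i], body_weight_kg = bw[i],
      V_l_per_kg = sp$V_l_per_kg, ka_per_h = sp$ka_per_h, ke_per_h = sp$ke_per_h)
  }
  list(
    dataset = study_dataset(profiles, doses,
                            groups = stats::setNames(
                              rep(sprintf("%gmgkg", params$dose_mg_per_kg), n), subjects)),
    truth = list(indices = dplyr::bind_rows(truth_rows),
                 subjects = dplyr::bind_rows(subj_param_rows),
                 params = params)
  )
}

apply_assay_error <- function(clean, params) {
  cv <- params$proportional_error_cv
  mult <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(length(clean), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, length(clean))
  addi <- if (params$additive_error_sd_ng_ml > 0)
    stats::rnorm(length(clean), 0, params$additive_error_sd_ng_ml) else 0
  pmax(clean * mult + addi, 0)
}

analytic_indices <- function(sp, analyte, subject) {
  amt <- sp$F_times_fa * sp$dose_mg_per_kg
  if (analyte == "parent") {
    ka <- sp$ka_per_h; ke <- sp$ke_per_h
    tmax <- if (abs(ka - ke) < 1e-9 * max(ka, ke)) 1 / ka else log(ka / ke) / (ka - ke)
    cmax <- parent_concentration(tmax, sp)
    auc <- amt / (sp$V_l_per_kg * ke) * MG_L_TO_NG_ML
  } else {
    met <- sp$metabolites[[analyte]]
    f <- function(t) metabolite_concentration(t, sp, analyte)
    opt <- stats::optimize(f, c(0, 20 / min(sp$ke_per_h, met$km_per_h)), maximum = TRUE)
    tmax <- opt$maximum; cmax <- opt$objective
    auc <- met$fm * amt / (met$Vm_l_per_kg * met$km_per_h) * MG_L_TO_NG_ML
  }
  tibble::tibble(subject = subject, analyte = analyte,
                 cmax_ng_ml = cmax, tmax_h = tmax, auc_0_inf = auc)
}
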