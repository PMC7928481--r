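test_that("parent and metabolite concentrations start at zero and stay non-negative", {
  p <- sim_params(rng_seed = 1)
  expect_equal(parent_concentration(0, p), 0)
  expect_equal(metabolite_concentration(0, p, "M1"), 0, tolerance = 1e-9)
  tt <- seq(0, 48, by = 0.5)
  expect_true(all(parent_concentration(tt, p) >= 0))
  expect_true(all(metabolite_concentration(tt, p, "M1") >= -1e-9))
})

test_that("parent Tmax matches the closed form ln(ka/ke)/(ka-ke)", {
  p <- sim_params(ka_per_h = 8, ke_per_h = 0.24, rng_seed = 1)
  tmax_analytic <- log(8 / 0.24) / (8 - 0.24)
  expect_equal(tmax_analytic, 0.452, tolerance = 1e-3)
  opt <- stats::optimize(function(t) parent_concentration(t, p), c(0, 6), maximum = TRUE)
  expect_equal(opt$maximum, tmax_analytic, tolerance = 1e-5)
})

test_that("numerical integrals of the closed forms match the analytic AUCs within 0.1%", {
  p <- sim_params(rng_seed = 1)
  auc_parent <- quad(function(t) parent_concentration(t, p), 0, 500)
  expect_equal(auc_parent,
               p$F_times_fa * p$dose_mg_per_kg / (p$V_l_per_kg * p$ke_per_h) * 1000,
               tolerance = 0.001)
  for (m in c("M1", "M2")) {
    met <- p$metabolites[[m]]
    auc_met <- quad(function(t) metabolite_concentration(t, p, m), 0, 3000)
    expect_equal(auc_met,
                 met$fm * p$F_times_fa * p$dose_mg_per_kg /
                   (met$Vm_l_per_kg * met$km_per_h) * 1000,
                 tolerance = 0.001)
  }
})

test_that("slow metabolite elimination yields the long apparent half-life", {
  expect_equal(log(2) / 0.028, 24.76, tolerance = 0.001)  # M1 preset terminal t1/2
  # and the simulated M1 terminal slope beats the parent's half-life
  s <- simulate_study(noiseless_params(n_subjects = 1,
                                       schedule_h = c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24, 48, 72)))
  prof <- s$dataset$profiles
  names(prof) <- vapply(prof, `[[`, character(1), "analyte")
  t_parent <- fit_terminal(prof[["parent"]])$t_half_h
  t_m1 <- fit_terminal(prof[["M1"]])$t_half_h
  expect_gt(t_m1, t_parent)
  expect_equal(t_m1, log(2) / 0.028, tolerance = 0.05)
})

test_that("the equal-rate absorption limit is continuous", {
  ke <- 0.24
  p_lim <- sim_params(ka_per_h = ke, ke_per_h = ke, rng_seed = 1)      # exact limit branch
  p_eps <- sim_params(ka_per_h = ke + 1e-6, ke_per_h = ke, rng_seed = 1)
  tt <- c(0.5, 1, 2, 5, 10)
  scale <- p_lim$dose_mg_per_kg / p_lim$V_l_per_kg * 1000
  expect_equal(parent_concentration(tt, p_lim), scale * ke * tt * exp(-ke * tt),
               tolerance = 1e-12)
  expect_equal(parent_concentration(tt, p_eps), parent_concentration(tt, p_lim),
               tolerance = 1e-5)
  # metabolite closed form requires distinct rates
  expect_error(metabolite_concentration(1, p_lim, "M1"), "pairwise distinct")
})

test_that("noiseless parent AUC obeys the mass-balance identity AUC*V*ke = F*D for every draw", {
  s <- simulate_study(sim_params(n_subjects = 6, between_subject_cv = 0.3,
                                 proportional_error_cv = 0, additive_error_sd_ng_ml = 0,
                                 rng_seed = 19))
  truth <- s$truth
  parent <- truth$indices[truth$indices$analyte == "parent", ]
  for (i in seq_len(nrow(parent))) {
    sp <- truth$subjects[truth$subjects$subject == parent$subject[i], ]
    expect_equal(parent$auc_0_inf[i] * sp$V_l_per_kg * sp$ke_per_h / 1000,
                 truth$params$F_times_fa * truth$params$dose_mg_per_kg,
                 tolerance = 1e-10)
  }
})

test_that("identical seeds give byte-identical datasets; different seeds differ", {
  prm <- sim_preset("koala-4mgkg", rng_seed = 123)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_concentration_csv(simulate_study(prm)$dataset, f1)
  write_concentration_csv(simulate_study(prm)$dataset, f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".csv")
  write_concentration_csv(simulate_study(sim_preset("koala-4mgkg", rng_seed = 124))$dataset, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("zero noise and zero between-subject variability collapse to the closed form", {
  prm <- noiseless_params(n_subjects = 3, rng_seed = 4)
  s <- simulate_study(prm)
  parents <- Filter(function(p) p$analyte == "parent", s$dataset$profiles)
  expected <- parent_concentration(prm$schedule_h, prm)
  for (p in parents) {
    obs <- ifelse(p$records$censored, NA_real_, p$records$conc_ng_ml)
    expect_equal(obs[!p$records$censored], expected[!p$records$censored],
                 tolerance = 1e-12)
    # censoring applies exactly where the model dips below the LLOQ
    expect_equal(p$records$censored, expected < prm$lloq_ng_ml)
  }
})

test_that("lowering the LLOQ never decreases the number of uncensored records", {
  n_uncensored <- function(lloq) {
    s <- simulate_study(sim_params(n_subjects = 3, lloq_ng_ml = lloq, rng_seed = 55))
    sum(vapply(s$dataset$profiles, function(p) sum(!p$records$censored), integer(1)))
  }
  counts <- vapply(c(100, 50, 15.63, 5, 0.1), n_uncensored, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("invalid simulation parameters are rejected before any sampling", {
  expect_error(sim_params(ke_per_h = -1), "positive")
  expect_error(sim_params(F_times_fa = 1.2), "\\(0, 1\\]")
  expect_error(sim_params(metabolites = list(
    M1 = list(fm = 0.7, km_per_h = 0.03, Vm_l_per_kg = 8),
    M2 = list(fm = 0.5, km_per_h = 0.09, Vm_l_per_kg = 8))), "sum to <= 1")
  expect_error(sim_params(schedule_h = c(1, 1, 2)), "strictly increasing")
  expect_error(sim_params(proportional_error_cv = -0.1), "non-negative")
})

test_that("NCA on the noiseless default preset recovers the kinetics the generator encodes", {
  prm <- noiseless_params(rng_seed = 8)
  s <- simulate_study(prm)
  prof <- s$dataset$profiles
  names(prof) <- vapply(prof, function(p) paste(p$subject_id, p$analyte, sep = "/"),
                        character(1))
  p1 <- prof[["S01/parent"]]
  r <- nca(p1, dose_for(s$dataset, "S01"))
  expect_equal(r$t_half_h, log(2) / prm$ke_per_h, tolerance = 0.05)
  ratio <- auc_trapezoid(prof[["S01/M1"]]) / auc_trapezoid(p1)
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 0.6)
})
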