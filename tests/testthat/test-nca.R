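test_that("observed peak reads straight from the data with earliest-time tie break", {
  p <- analyte_profile("S", "x", c(0.5, 1, 2, 4), c(10, 50, 50, 20))
  pk <- observed_peak(p)
  expect_equal(pk$cmax_ng_ml, 50)
  expect_equal(pk$tmax_h, 1)

  single <- analyte_profile("S", "x", 1, 50)
  expect_equal(observed_peak(single), list(cmax_ng_ml = 50, tmax_h = 1))

  cen <- analyte_profile("S", "x", c(1, 2), c(NA, NA), censored = c(TRUE, TRUE))
  expect_error(observed_peak(cen), "no uncensored")

  # censored records never win the peak
  p2 <- analyte_profile("S", "x", c(1, 2), c(NA, 30), censored = c(TRUE, FALSE))
  expect_equal(observed_peak(p2)$cmax_ng_ml, 30)
})

test_that("terminal regression recovers a noiseless mono-exponential exactly", {
  p <- mono_profile(c0 = 100, ke = 0.2)
  f <- fit_terminal(p)
  expect_equal(f$kel_per_h, 0.2, tolerance = 1e-10)
  expect_equal(f$t_half_h, log(2) / 0.2, tolerance = 1e-10)
  expect_equal(f$t_half_h * f$kel_per_h, log(2))
  # the whole post-Tmax suffix is selected when the fit is perfect throughout
  expect_equal(f$point_times, STUDY_SCHEDULE[-1])

  # kel = ln 2 gives a one-hour half-life by definition
  f2 <- fit_terminal(mono_profile(ke = log(2)))
  expect_equal(f2$t_half_h, 1, tolerance = 1e-10)
})

test_that("automatic selection skips the absorption phase; explicit points override it", {
  p <- bateman_profile(ka = 1.2, ke = 0.25)  # slow absorption contaminates early points
  f <- fit_terminal(p)
  expect_gt(min(f$point_times), observed_peak(p)$tmax_h)
  expect_gte(f$n_points, 3)
  # true elimination recovered from the late suffix
  expect_equal(f$kel_per_h, 0.25, tolerance = 0.05)

  f3 <- fit_terminal(p, point_times = c(6, 8, 12))
  expect_equal(f3$point_times, c(6, 8, 12))
  f2 <- fit_terminal(p, point_times = c(8, 12))  # manual 2-point override allowed
  expect_equal(f2$n_points, 2)
  expect_error(fit_terminal(p, point_times = c(3, 8, 12)), "not observed")
})

test_that("degenerate terminal phases raise informative errors", {
  rising <- analyte_profile("S", "x", c(1, 2, 4, 8, 12), c(1, 2, 4, 8, 12))
  expect_error(fit_terminal(rising), "non-negative slope|insufficient")
  short <- analyte_profile("S", "x", c(1, 2, 4), c(10, 8, 5))
  expect_error(fit_terminal(short), "insufficient data")  # only 2 points after Tmax
})

test_that("trapezoid increments follow the linear-up/log-down interval rule", {
  # strictly falling interval: log trapezoid equals the exact integral of
  # the interpolating exponential
  p <- analyte_profile("S", "x", c(1, 2), c(100, 50))
  expect_equal(auc_trapezoid(p), 50 / log(2), tolerance = 1e-12)
  k <- log(100 / 50) / 1
  oracle <- quad(function(t) 100 * exp(-k * (t - 1)), 1, 2)
  expect_equal(auc_trapezoid(p), oracle, tolerance = 1e-8)
  expect_equal(auc_trapezoid(p, "linear"), 75)

  # flat segment: both methods give the constant rectangle
  flat <- analyte_profile("S", "x", c(1, 2), c(100, 100))
  expect_equal(auc_trapezoid(flat), 100)
  expect_equal(auc_trapezoid(flat, "linear"), 100)

  # rising interval uses the arithmetic trapezoid under both methods
  up <- analyte_profile("S", "x", c(0, 1), c(0, 100))
  expect_equal(auc_trapezoid(up), 50)
})

test_that("log-down AUC equals the analytic piecewise-exponential integral to machine precision", {
  p <- mono_profile(c0 = 250, ke = 0.31)
  t <- p$records$time_h
  analytic <- 250 / 0.31 * (exp(-0.31 * t[1]) - exp(-0.31 * t[length(t)]))
  expect_equal(auc_trapezoid(p), analytic, tolerance = 1e-12)

  # AUMC log-down increment matches numerical quadrature of t * C(t)
  aumc_analytic <- quad(function(s) s * 250 * exp(-0.31 * s), t[1], t[length(t)])
  expect_equal(aumc_trapezoid(p), aumc_analytic, tolerance = 1e-8)
})

test_that("both trapezoid methods converge to quadrature as sampling densifies", {
  f <- function(t) 500 * 8 / (8 - 0.24) * (exp(-0.24 * t) - exp(-8 * t))
  dense <- seq(0.001, 12, by = 0.001)
  p <- analyte_profile("S", "x", dense, f(dense))
  truth <- quad(f, 0.001, 12)
  expect_equal(auc_trapezoid(p), truth, tolerance = 1e-6)
  expect_equal(auc_trapezoid(p, "linear"), truth, tolerance = 1e-6)
})

test_that("censored records are zero before Tmax and excluded at or after it", {
  p <- analyte_profile("S", "x", c(0.25, 0.5, 1, 2, 4, 6),
                       c(NA, 80, 100, 50, NA, 12),
                       censored = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  pts <- koalapk:::nca_points(p)
  expect_equal(pts$time_h, c(0.25, 0.5, 1, 2, 6))   # 4 h BLQ dropped (post-Tmax)
  expect_equal(pts$conc_ng_ml[1], 0)                 # 0.25 h BLQ imputed as 0
})

test_that("extrapolation to infinity adds the analytic terminal tail", {
  # limit clast -> 0 leaves AUC unchanged
  e0 <- extrapolate_to_infinity(100, 400, 0, 12, 0.3)
  expect_equal(e0$auc_0_inf, 100)
  expect_equal(e0$aumc_0_inf, 400)
  expect_error(extrapolate_to_infinity(100, 400, 10, 12, -0.1), "positive")

  # published K1 profile endpoint reproduces the printed AUC0-inf
  kel <- log(2) / 2.16
  e <- extrapolate_to_infinity(692.37, 0, 13.87, 12, kel)
  expect_equal(e$auc_0_inf, 735.72, tolerance = 0.001)

  # mono-exponential: trapezoid + analytic tail equals the closed-form
  # integral from the first sample to infinity
  p <- mono_profile(c0 = 100, ke = 0.2, times = seq(0.25, 12, by = 0.25))
  clast <- 100 * exp(-0.2 * 12)
  tot <- auc_trapezoid(p) + clast / 0.2
  expect_equal(tot, 100 / 0.2 * exp(-0.2 * 0.25), tolerance = 1e-10)
})

test_that("derived indices reproduce the published K1 values from printed inputs", {
  d <- dose_event("K1", dose_mg = 18.2, body_weight_kg = 9.1, route = "sc")
  kel <- log(2) / 2.16
  idx <- derive_indices(735.72, 1929.46, d, kel, cmax = 387.81, auc_0_tlast = 692.37)
  expect_equal(idx$cl_over_f_l_kg_h, 2.72, tolerance = 0.01)
  expect_equal(idx$cl_over_f_ml_min_kg, 45.31, tolerance = 0.01)
  expect_equal(idx$vz_over_f_l_kg, 8.49, tolerance = 0.01)
  expect_equal(idx$mrt_h, 2.62, tolerance = 0.01)
  expect_equal(idx$cmax_per_dose, 21.31, tolerance = 0.001)
  # internal consistency: unit conversion and Vz = Cl/kel by construction
  expect_equal(idx$cl_over_f_ml_min_kg, idx$cl_over_f_l_kg_h * 1000 / 60)
  expect_equal(idx$vz_over_f_l_kg, idx$cl_over_f_l_kg_h / kel)
})

test_that("NCA is scale-equivariant in concentration", {
  base <- bateman_profile()
  d <- dose_event("S1", 30, 7.5, "sc")
  r0 <- nca(base, d)
  for (c_mult in c(0.5, 3, 10)) {
    ps <- analyte_profile("S1", "parent", base$records$time_h,
                          base$records$conc_ng_ml * c_mult)
    r <- nca(ps, d)
    expect_equal(r$cmax_ng_ml, r0$cmax_ng_ml * c_mult)
    expect_equal(r$auc_0_tlast, r0$auc_0_tlast * c_mult)
    expect_equal(r$aumc_0_inf, r0$aumc_0_inf * c_mult)
    expect_equal(r$kel_per_h, r0$kel_per_h, tolerance = 1e-10)
    expect_equal(r$tmax_h, r0$tmax_h)
    expect_equal(r$mrt_h, r0$mrt_h, tolerance = 1e-10)
    expect_equal(r$cl_over_f_l_kg_h, r0$cl_over_f_l_kg_h / c_mult, tolerance = 1e-10)
    expect_equal(r$vz_over_f_l_kg, r0$vz_over_f_l_kg / c_mult, tolerance = 1e-10)
  }
})

test_that("AUC0-inf >= AUC0-tlast and MRT > 0 across simulated profiles", {
  sim <- simulate_study(sim_preset("koala-4mgkg", rng_seed = 33))
  for (p in sim$dataset$profiles) {
    ok <- sum(!p$records$censored & p$records$conc_ng_ml > 0, na.rm = TRUE)
    if (ok < 4) next
    r <- tryCatch(nca(p, dose_for(sim$dataset, p$subject_id)),
                  error = function(e) NULL)
    if (is.null(r)) next  # noisy profile without a clean terminal phase
    expect_gte(r$auc_0_inf, r$auc_0_tlast)
    expect_gt(r$mrt_h, 0)
  }
})

test_that("group summaries agree with a brute-force sort-based oracle", {
  set.seed(401)
  for (n in c(1, 2, 3, 4, 7, 10)) {
    v <- round(stats::rlnorm(n, 3, 1), 3)
    s <- summarize_group(v)
    sv <- sort(v)
    med_oracle <- if (n %% 2 == 1) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
    expect_equal(s$median, med_oracle)
    expect_equal(s$mean, sum(v) / n)
    if (n > 1) {
      expect_equal(s$sd, sqrt(sum((v - mean(v))^2) / (n - 1)))
    } else {
      expect_true(is.na(s$sd))  # SD undefined for a single value
    }
    expect_equal(s$min, sv[1]); expect_equal(s$max, sv[n]); expect_equal(s$n, n)
  }
})

test_that("group summaries reproduce the published medians and mean +/- SD", {
  cmax_4 <- c(707.85, 843.13, 784.89, 728.85)
  expect_equal(summarize_group(cmax_4)$median, 756.87)
  thalf_4 <- c(1.31, 3.53, 3.39, 2.39)
  expect_equal(summarize_group(thalf_4)$median, 2.89)
  expect_equal(summarize_group(thalf_4)$mean, 2.65, tolerance = 0.005)
  cl_all <- c(45.31, 22.16, 61.01, 34.04, 42.03, 31.84)
  s <- summarize_group(cl_all)
  expect_equal(s$mean, 39.40, tolerance = 0.001)
  expect_equal(s$sd, 13.36, tolerance = 0.001)
})
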