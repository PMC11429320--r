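test_that("molar/mass conversion follows the molecular weight", {
  expect_equal(ifxpbpk:::mgL_to_nmolL(1, 149.9), 6.671, tolerance = 1e-4)
  expect_equal(ifxpbpk:::nmolL_to_mgL(ifxpbpk:::mgL_to_nmolL(3.7, 149.9),
                                      149.9), 3.7)
})

test_that("missing calibration constants are a configuration error", {
  expect_error(pbpk_model(virtual_individual(30, 70), calibration = NULL),
               "calibration")
})

test_that("disease state selects the endosomal clearance default", {
  expect_equal(adult_healthy_model()$system$cl_endo_spec, 0.91)
  expect_equal(adult_ibd_model()$system$cl_endo_spec, 1.6)
})

test_that("pre-dose equilibrium is stationary and puts TNF at reference", {
  mod <- adult_healthy_model()
  st <- equilibrate(mod, verify = TRUE)
  expect_lt(attr(st, "drift"), 1e-3)
  # free TNF-alpha concentration = 0.20 pmol/L
  expect_equal(st[["tnf"]] / mod$k$vp * 1000, 0.20, tolerance = 1e-10)
  # drug states empty
  expect_true(all(st[c("depot", "plasma", "interstitial", "endosome_free",
                       "endosome_fcrn_bound")] == 0))
  # FcRn conservation: free + IgG-bound = total (no drug present)
  expect_equal(attr(st, "fcrn_free") + attr(st, "igg_fcrn_bound"),
               mod$k$rtot)
})

test_that("IgG-FcRn occupancy matches the independent binding solution", {
  mod <- adult_healthy_model()
  st <- equilibrate(mod)
  # independent route: kinetic steady state of mass-action binding with
  # recycling loss, GR = kon G (Rtot - GR) / (koff + krec)
  kon_g <- 0.87 * 60; koff_g <- kon_g * 0.63; krec <- 0.30 * 60
  g <- mod$k$g_endo
  a <- kon_g * g / (koff_g + krec)
  gr_expected <- a / (1 + a) * mod$k$rtot
  expect_equal(attr(st, "igg_fcrn_bound"), gr_expected, tolerance = 1e-12)

  # no endogenous IgG -> all FcRn free
  sys0 <- system_parameters(igg_plasma_conc = 0,
                            fcrn_endo_conc = 100, k_dist = 0.1)
  mod0 <- pbpk_model(virtual_individual(30, 70), system = sys0,
                     calibration = NULL)
  st0 <- equilibrate(mod0)
  expect_equal(attr(st0, "fcrn_free"), mod0$k$rtot)
})

test_that("no dose means no drug anywhere", {
  mod <- adult_healthy_model()
  st <- equilibrate(mod)
  out <- ifxpbpk:::integrate_segment(mod, st, times = seq(0, 500, 50),
                                     inf_rate = 0, rtol = 1e-8,
                                     atol = 1e-10)
  expect_true(all(abs(out[, "plasma"]) < 1e-12))
  expect_true(all(abs(out[, "eliminated"]) < 1e-12))
})

test_that("a closed system (no catabolism, full recycling) conserves drug", {
  sys <- system_parameters(cl_endo_spec = 0, fcrn_endo_conc = 100,
                           k_dist = 0.1)
  mod <- pbpk_model(virtual_individual(30, 70), system = sys,
                    calibration = NULL)
  prof <- simulate(mod, regimen = single_iv_regimen(), end_time = 500)
  st <- attr(prof, "states")
  expect_lt(max(st[, "eliminated"]), 1e-9)
  total <- rowSums(st[, c("plasma", "interstitial", "endosome_free",
                          "endosome_fcrn_bound")])
  dose_nmol <- ifxpbpk:::mg_to_nmol(350, 149.9)
  expect_lt(max(abs(total[prof$time >= 2] - dose_nmol)) / dose_nmol, 1e-6)
})

test_that("Cmax occurs at the end of the 2-h infusion", {
  prof <- s1_profile()
  expect_equal(prof$time[which.max(prof$conc)], 2)
})

test_that("mass balance holds to 1e-6 at all reported times", {
  expect_lt(max(attr(s1_profile(), "mass_balance_error")), 1e-6)
  expect_lt(max(attr(s2_profile(), "mass_balance_error")), 1e-6)
  expect_true(min(attr(s2_profile(), "states")) > -1e-8)  # non-negativity
})

test_that("disposition is dose-linear across 0.1x to 10x", {
  mod <- adult_ibd_model()
  base <- iv_standard(70, 5, 14)
  grid <- seq(0, 20 * 168, by = 24)
  ref <- simulate(mod, regimen = base, end_time = 20 * 168, t_grid = grid)
  # within 1% over the clinical dose range; at 10x (50 mg/kg) partial
  # FcRn occupancy by the drug bends linearity slightly (~2%)
  for (f in c(0.1, 2, 10)) {
    scaled <- base
    scaled$events$amount <- scaled$events$amount * f
    prof <- simulate(mod, regimen = scaled, end_time = 20 * 168,
                     t_grid = grid)
    keep <- ref$conc > 1e-6
    tol <- if (f > 2) 0.03 else 0.01
    expect_lt(max(abs(prof$conc[keep] / ref$conc[keep] - f) / f), tol)
  }
})

test_that("increasing endosomal clearance strictly decreases exposure", {
  cal <- shipped_calibration()
  aucs <- vapply(c(0.91, 1.6, 3.2), function(cl) {
    sys <- system_parameters(cl_endo_spec = cl)
    mod <- pbpk_model(virtual_individual(40, 70, "ibd"), system = sys,
                      calibration = cal)
    unname(ifxpbpk:::linear_iv_metrics(mod, 350)[["auc_inf"]])
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
  # IBD (1.6/min) exposure strictly below healthy (0.91/min), same regimen
  m_h <- nca(s1_profile(), dose = 350)
  prof_i <- simulate(adult_ibd_model(), regimen = single_iv_regimen(),
                     end_time = 5000)
  m_i <- nca(prof_i, dose = 350)
  expect_lt(m_i$auc_inf, m_h$auc_inf)
})

test_that("SC depot input is bioavailability-corrected and fully absorbed", {
  mod <- adult_ibd_model()
  ev <- data.frame(time = 0, route = "sc", amount = 120, duration = NA)
  t_end <- 14 * log(2) / 0.0114          # 14 absorption half-lives
  reg <- regimen(ev, horizon = t_end)
  prof <- simulate(mod, regimen = reg, end_time = t_end)
  st <- attr(prof, "states")
  dose_nmol <- ifxpbpk:::mg_to_nmol(0.79 * 120, 149.9)  # 94.8 mg
  expect_equal(unname(st[1, "depot"]), dose_nmol, tolerance = 1e-9)
  absorbed <- dose_nmol - st[nrow(st), "depot"]
  expect_lt(abs(absorbed - dose_nmol) / dose_nmol, 1e-4)
})

test_that("the linearised model matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  mod <- pbpk_model(virtual_individual(40, 70, "ibd"),
                    calibration = shipped_calibration(),
                    tnf_mode = "off", clamp_fcrn = TRUE)
  A <- drug_rate_matrix(mod)
  rate <- ifxpbpk:::mg_to_nmol(350, 149.9) / 2
  b <- c(0, rate, 0, 0, 0)
  # x(t) = A^-1 (e^{At} - I) b during the infusion, then homogeneous
  x_inf <- function(t) {
    E <- as.matrix(Matrix::expm(A * t))
    drop(solve(A, (E - diag(5)) %*% b))
  }
  x2 <- x_inf(2)
  ts <- c(1, 2, 24, 168, 1000, 3000)
  expected <- vapply(ts, function(t) {
    x <- if (t <= 2) x_inf(t) else
      drop(as.matrix(Matrix::expm(A * (t - 2))) %*% x2)
    x[2] / mod$k$vp
  }, numeric(1))
  prof <- simulate(mod, regimen = single_iv_regimen(), end_time = 3000)
  sim <- approx(prof$time, prof$conc, xout = ts)$y
  sim_nmolL <- ifxpbpk:::mgL_to_nmolL(sim, 149.9)
  expect_lt(max(abs(sim_nmolL / expected - 1)), 1e-3)
})

test_that("reported metrics are converged in the solver tolerance", {
  mod <- adult_ibd_model()
  reg <- iv_standard(70, 5, 14)
  p1 <- simulate(mod, regimen = reg, end_time = 16 * 168,
                 rtol = 1e-8, atol = 1e-10)
  p2 <- simulate(mod, regimen = reg, end_time = 16 * 168,
                 rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(max(p1$conc) / max(p2$conc) - 1), 1e-4)
  t14 <- trough_at_weeks(p1, 14)$conc
  t14b <- trough_at_weeks(p2, 14)$conc
  expect_lt(abs(t14 / t14b - 1), 1e-4)
})

test_that("quasi-equilibrium and mass-action target binding agree", {
  cal <- shipped_calibration()
  ind <- virtual_individual(30, 70)
  # slow the TNF off-rate so explicit kinetics are integrable; binding
  # equilibrium (kon/koff) is unchanged
  drg <- drug_parameters(koff_tnf = 1.33e-6)
  m_qe <- pbpk_model(ind, drg, calibration = cal, tnf_mode = "qe")
  m_ma <- pbpk_model(ind, drg, calibration = cal, tnf_mode = "mass_action")
  grid <- seq(0, 1000, by = 10)
  p_qe <- simulate(m_qe, regimen = single_iv_regimen(), end_time = 1000,
                   t_grid = grid)
  p_ma <- simulate(m_ma, regimen = single_iv_regimen(), end_time = 1000,
                   t_grid = grid)
  keep <- p_qe$conc > 1e-6
  expect_lt(max(abs(p_ma$conc[keep] / p_qe$conc[keep] - 1)), 1e-3)
})
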