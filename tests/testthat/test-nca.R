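test_that("trapezoidal AUC reproduces closed forms", {
  flat <- concentration_profile(0:10, rep(1, 11))
  expect_equal(auc_trapezoid(flat), 10)

  k <- log(2) / 240
  t <- seq(0, 4000, by = 1)
  mono <- concentration_profile(t, 100 * exp(-k * t))
  m <- nca(mono, dose = NULL, washout_after = 0)
  auc_inf <- auc_trapezoid(mono) +
    mono$conc[length(t)] / terminal_slope(mono)$lambda_z
  expect_rel(auc_inf, 100 / k, 0.001)
})

test_that("AUC is additive over concatenated intervals", {
  t <- seq(0, 300, by = 2.5)
  prof <- concentration_profile(t, 50 * exp(-0.01 * t) + 5)
  whole <- auc_trapezoid(prof)
  parts <- auc_trapezoid(prof, from = 0, to = 100) +
    auc_trapezoid(prof, from = 100, to = 300)
  expect_equal(whole, parts)
})

test_that("clearance from the printed trial values rounds to 0.01 L/h", {
  cl <- 350 / 38000
  expect_equal(round(cl, 2), 0.01)
  expect_equal(cl, 0.0092105, tolerance = 1e-4)
})

test_that("terminal slope finds exact and biexponential half-lives", {
  t <- seq(0, 6000, by = 24)
  pure <- concentration_profile(t, 20 * exp(-log(2) / (10 * 24) * t))
  expect_equal(terminal_slope(pure)$t_half_days, 10, tolerance = 1e-9)

  bi <- concentration_profile(t, 50 * exp(-0.1 * t) + 50 * exp(-0.001 * t))
  expect_rel(terminal_slope(bi)$t_half_days, log(2) / 0.001 / 24, 0.001)
  # = 28.88 days

  short <- concentration_profile(c(1, 2, 3, 4), exp(-(1:4)))
  expect_error(terminal_slope(short), "at least 5")
})

test_that("troughs are pre-dose samples; dose-free weeks are flagged", {
  doses <- seq(0, 30, by = 2) * 168
  k <- 0.002
  t <- sort(unique(c(seq(0, 30 * 168, by = 4), doses - 1e-6)))
  t <- t[t >= 0]
  conc <- rowSums(vapply(doses, function(td)
    ifelse(t - td <= 0, 0, 10 * exp(-k * (t - td))), numeric(length(t))))
  prof <- concentration_profile(t, conc)
  tr <- trough_at_weeks(prof, c(10, 11), dose_times = doses)
  expect_false(tr$non_trough[1])
  expect_true(tr$non_trough[2])          # no dose at week 11
  # sawtooth closed form: sum of residues of all previous doses just
  # before the week-10 dose
  expected <- sum(10 * exp(-k * (10 * 168 - doses[doses < 10 * 168])))
  expect_rel(tr$conc[1], expected, 1e-4)

  flat <- concentration_profile(seq(0, 5000, 100), rep(5, 51))
  expect_equal(trough_at_weeks(flat, 4, dose_times = 4 * 168)$conc, 5)
})

test_that("metrics are stable under grid refinement", {
  par <- list(v1 = 2.8, k10 = 0.003, k12 = 0.02, k21 = 0.02)
  f <- function(h) {
    t <- seq(0, 3000, by = h)
    conc <- ifxpbpk:::conc_2cpt_inf(t, 350, 2, par$v1, par$k10, par$k12,
                                    par$k21)
    p <- concentration_profile(t, conc)
    c(auc = auc_trapezoid(p), cmax = max(p$conc))
  }
  a <- f(0.5); b <- f(0.25)
  expect_lt(abs(a[["auc"]] / b[["auc"]] - 1), 5e-4)
  expect_lt(abs(a[["cmax"]] / b[["cmax"]] - 1), 5e-4)
})

test_that("single-dose IV bundle is internally consistent", {
  m <- nca(s1_profile(), dose = 350)
  expect_equal(m$cl * m$auc_inf, 350)            # CL defined by dose/AUC
  expect_equal(m$vz, m$cl / m$lambda_z)
  expect_gt(m$auc_inf, m$auc_last)
  expect_gt(m$vz, m$vss * 0.9)                   # Vz >= Vss up to tolerance
})
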