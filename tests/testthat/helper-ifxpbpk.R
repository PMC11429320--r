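# shared fixtures, built once per test session and memoised

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

shipped_calibration <- function() fixture("cal", function() read_calibration())

adult_healthy_model <- function() fixture("mod_healthy", function()
  pbpk_model(virtual_individual(30, 70, "healthy"),
             calibration = shipped_calibration()))

adult_ibd_model <- function() fixture("mod_ibd", function()
  pbpk_model(virtual_individual(40, 70, "ibd"),
             calibration = shipped_calibration()))

single_iv_regimen <- function(body_weight = 70) {
  reg <- iv_standard(body_weight, 5, 6)
  reg$events <- reg$events[1, , drop = FALSE]
  reg
}

# healthy single-dose profile with washout (used by several files)
s1_profile <- function() fixture("s1_prof", function()
  simulate(adult_healthy_model(), regimen = single_iv_regimen(),
           end_time = 5000))

# IBD multidose profile to week 30, simulated to week 54 (washout)
s2_profile <- function() fixture("s2_prof", function()
  simulate(adult_ibd_model(), regimen = iv_standard(70, 5, 30),
           end_time = 54 * 168))

build_cfg_individual <- function(cfg) {
  ifxpbpk:::build_scenario_individual(cfg)
}

expect_rel <- function(actual, target, tol) {
  expect_true(abs(actual / target - 1) <= tol,
              label = sprintf("%.6g vs target %.6g (rel err %.3g, tol %.3g)",
                              actual, target, abs(actual / target - 1), tol))
}

fit_obs_regimen <- function() single_iv_regimen()

fit_obs_times <- c(2, 8, 24, 72, 168, 336, 504, 672, 840, 1008, 1176, 1344)

make_obs <- function(cl_endo = 0.91, noise_cv = 0, seed = 1,
                     dose_factor = 1) {
  cal <- shipped_calibration()
  sys <- system_parameters(cl_endo_spec = cl_endo)
  mod <- pbpk_model(virtual_individual(30, 70), system = sys,
                    calibration = cal)
  reg <- fit_obs_regimen()
  reg$events$amount <- reg$events$amount * dose_factor
  prof <- simulate(mod, regimen = reg, end_time = max(fit_obs_times),
                   t_grid = sort(unique(c(0, fit_obs_times))))
  conc <- prof$conc[match(fit_obs_times, prof$time)]
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    set.seed(seed)
    conc <- conc * rlnorm(length(conc), 0, sdlog)
  }
  concentration_profile(fit_obs_times, conc)
}

template_model <- function() adult_healthy_model()

# Monte-Carlo clearance recovery at CV 15% over a fixed seed set
recovery_errors <- function() fixture("mc_recovery", function() {
  vapply(1:12, function(s) {
    obs <- make_obs(noise_cv = 0.15, seed = s)
    f <- fit_parameters(template_model(), obs, fit_obs_regimen(),
                        fit_spec(list(cl_endo_spec = c(0.05, 10))))
    f$estimates[["cl_endo_spec"]] / 0.91 - 1
  }, numeric(1))
})
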