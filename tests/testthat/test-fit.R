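test_that("noise-free self-generated data recover the clearance exactly", {
  obs <- make_obs()
  f <- fit_parameters(template_model(), obs, fit_obs_regimen(),
                      fit_spec(list(cl_endo_spec = c(0.05, 10))))
  expect_true(f$converged)
  expect_rel(f$estimates[["cl_endo_spec"]], 0.91, 0.01)
})

test_that("estimates are invariant to joint dose/concentration scaling", {
  obs1 <- make_obs()
  obs2 <- concentration_profile(obs1$time, obs1$conc * 2)
  reg2 <- fit_obs_regimen()
  reg2$events$amount <- reg2$events$amount * 2
  f1 <- fit_parameters(template_model(), obs1, fit_obs_regimen(),
                       fit_spec(list(cl_endo_spec = c(0.05, 10))))
  f2 <- fit_parameters(template_model(), obs2, reg2,
                       fit_spec(list(cl_endo_spec = c(0.05, 10))))
  # equal up to the (sub-0.1%) FcRn-occupancy nonlinearity of the model
  expect_equal(f1$estimates, f2$estimates, tolerance = 2e-3)
})

test_that("noisy data (CV 15%) recover the clearance accurately", {
  errs <- recovery_errors()
  expect_lt(abs(mean(errs)), 0.02)          # bias
  expect_lt(sqrt(mean(errs^2)), 0.10)       # RMSE
  obs <- make_obs(noise_cv = 0.15, seed = 1)
  f <- fit_parameters(template_model(), obs, fit_obs_regimen(),
                      fit_spec(list(cl_endo_spec = c(0.05, 10))))
  expect_true(is.finite(f$uncertainty[["cl_endo_spec"]]))
})

test_that("healthy/IBD paired fits recover the clearance ratio", {
  spec <- fit_spec(list(cl_endo_spec = c(0.05, 10)))
  f_h <- fit_parameters(template_model(), make_obs(0.91), fit_obs_regimen(),
                        spec)
  f_i <- fit_parameters(template_model(), make_obs(1.6), fit_obs_regimen(),
                        spec)
  ratio <- f_i$estimates[["cl_endo_spec"]] / f_h$estimates[["cl_endo_spec"]]
  expect_rel(ratio, 1.6 / 0.91, 0.02)
})

test_that("estimates respect bounds and failures are penalised not fatal", {
  obs <- make_obs()
  f <- fit_parameters(template_model(), obs, fit_obs_regimen(),
                      fit_spec(list(cl_endo_spec = c(1.2, 10))))
  expect_gte(f$estimates[["cl_endo_spec"]], 1.2)
  expect_error(fit_spec(list(cl_endo_spec = c(-1, 2))), "bounds")
})
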