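test_that("noise-free healthy reference reproduces the trial metrics", {
  sp <- synthetic_trial_spec(cv = 0,
                             times = c(seq(0, 2, 0.1), seq(2.2, 6000, 2)))
  prof <- generate_synthetic_trial(sp)
  m <- nca(prof, dose = 350, body_weight = 70, washout_after = 2)
  expect_rel(m$cl, 350 / 38000, 0.01)      # prints as 0.01 L/h
  expect_rel(m$cmax, 121, 0.01)
  expect_rel(m$vz_per_kg, 0.09, 0.01)
  expect_rel(m$auc_inf, 38000, 0.01)
})

test_that("generation is reproducible under a fixed seed", {
  a <- generate_synthetic_trial(synthetic_trial_spec(cv = 0.15, seed = 11))
  b <- generate_synthetic_trial(synthetic_trial_spec(cv = 0.15, seed = 11))
  expect_identical(a$conc, b$conc)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_profile_csv(a, f1); write_profile_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  # and the RNG state of the session is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_synthetic_trial(
    synthetic_trial_spec(cv = 0.15, seed = 3)))
  expect_identical(runif(1), before)
})

test_that("the proportional noise model has the configured CV", {
  reps <- vapply(1:1000, function(s)
    generate_synthetic_trial(synthetic_trial_spec(cv = 0.15, seed = s,
                                                  times = 24))$conc,
    numeric(1))
  expect_rel(sd(reps) / mean(reps), 0.15, 0.10)
})

test_that("IBD multidose reference has the published terminal half-life", {
  sp <- synthetic_trial_spec("ibd_multidose_iv", cv = 0, horizon_weeks = 30,
                             times = seq(30 * 168, 60 * 168, by = 24))
  prof <- generate_synthetic_trial(sp)
  expect_rel(terminal_slope(prof)$t_half_days, 9.5, 0.001)
})

test_that("SC switch trough series sits on the clinical trough scale", {
  prof <- generate_synthetic_trial(
    synthetic_trial_spec("sc_switch_troughs", cv = 0))
  late <- prof$conc[prof$time >= 20 * 168]
  expect_true(all(late > 5 & late < 30))
})

test_that("the observations CSV round-trips through the reader", {
  prof <- generate_synthetic_trial(synthetic_trial_spec(cv = 0.1, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- read_profile_csv(path)
  expect_equal(back$time, prof$time)
  expect_equal(back$conc, prof$conc, tolerance = 1e-12)
  unlink(path)
})
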