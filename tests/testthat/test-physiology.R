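test_that("compartment volumes scale linearly with body weight", {
  a70 <- virtual_individual(30, 70, "healthy")
  expect_equal(a70$v_plasma, 70 * 0.0414)
  expect_equal(a70$v_interstitial, 70 * 0.16)
  expect_equal(a70$v_endosomal, 0.20 * 0.5)

  a140 <- virtual_individual(30, 140, "healthy")
  expect_equal(a140$v_plasma, 2 * a70$v_plasma)

  child <- virtual_individual(14, 60, "ibd")
  r <- 60 / 70
  expect_equal(child$v_plasma, r * a70$v_plasma)
  expect_equal(child$v_interstitial, r * a70$v_interstitial)
  expect_equal(child$v_endosomal, r * a70$v_endosomal)
  expect_identical(child$disease_state, "ibd")

  # identical inputs give identical individuals
  expect_identical(unclass(virtual_individual(14, 60, "ibd")),
                   unclass(child))
})

test_that("out-of-range biometrics raise errors naming the field", {
  expect_error(virtual_individual(150, 70), "age")
  expect_error(virtual_individual(30, 1), "body_weight")
  expect_error(virtual_individual(30, 400), "body_weight")
})

test_that("configurable scaling exponents are honoured", {
  a <- virtual_individual(30, 35, exponents = c(endosomal = 0.75))
  expect_equal(a$v_endosomal, 0.20 * 0.5 * (35 / 70)^0.75)
  expect_equal(a$v_plasma, 35 * 0.0414)  # others stay linear
})

test_that("population sampling truncates hard and reproduces under seed", {
  spec <- population_spec(50, weight_band = c(45, 70), seed = 1)
  pop <- sample_population(spec)
  expect_length(pop, 50)
  w <- vapply(pop, function(p) p$body_weight, numeric(1))
  a <- vapply(pop, function(p) p$age, numeric(1))
  expect_true(all(w >= 45 & w <= 70))
  expect_true(all(a >= 6 & a <= 18))

  pop2 <- sample_population(spec)
  expect_identical(w, vapply(pop2, function(p) p$body_weight, numeric(1)))

  # a different seed gives a different draw
  pop3 <- sample_population(population_spec(50, weight_band = c(45, 70),
                                            seed = 2))
  expect_false(identical(w, vapply(pop3, function(p) p$body_weight,
                                   numeric(1))))
})

test_that("empirical band weight mean matches the quadrature oracle", {
  cv <- 0.15
  band <- c(20, 30)
  spec <- population_spec(10000, weight_band = band, weight_cv = cv,
                          seed = 7)
  pop <- sample_population(spec)
  w <- vapply(pop, function(p) p$body_weight, numeric(1))
  expect_true(min(w) >= band[1] && max(w) <= band[2])

  # oracle: mean of the sampling distribution by numerical integration
  # over the uniform age window, truncated-lognormal mean in closed form
  sdlog <- sqrt(log(1 + cv^2))
  anchor <- function(age) 20 + (age - 6) * (50 / 12)
  anchor_age <- function(wt) 6 + (wt - 20) * (12 / 50)
  a_lo <- max(6, anchor_age(band[1] / exp(3 * sdlog)))
  a_hi <- min(18, anchor_age(band[2] * exp(3 * sdlog)))
  mean_trunc <- function(age) {
    mu <- log(anchor(age)) - sdlog^2 / 2
    za <- (log(band[1]) - mu) / sdlog
    zb <- (log(band[2]) - mu) / sdlog
    denom <- pnorm(zb) - pnorm(za)
    exp(mu + sdlog^2 / 2) *
      (pnorm(zb - sdlog) - pnorm(za - sdlog)) / denom
  }
  oracle <- stats::integrate(function(a) vapply(a, mean_trunc, 0),
                             a_lo, a_hi)$value / (a_hi - a_lo)
  expect_rel(mean(w), oracle, 0.02)
})

test_that("infeasible band/age intersection is a configuration error", {
  spec <- population_spec(10, age_range = c(17, 18),
                          weight_band = c(5, 8), weight_cv = 0.05)
  expect_error(sample_population(spec), "unreachable")
})

test_that("populations serialize to the documented CSV layout", {
  pop <- sample_population(population_spec(5, weight_band = c(30, 45),
                                           seed = 3))
  path <- tempfile(fileext = ".csv")
  write_population_csv(pop, path)
  df <- read.csv(path)
  expect_identical(names(df),
                   c("id", "age_y", "weight_kg", "v_plasma_L",
                     "v_interstitial_L", "v_endosomal_L", "disease_state"))
  expect_equal(nrow(df), 5)
  expect_equal(df$v_plasma_L, df$weight_kg * 0.0414, tolerance = 1e-12)
  unlink(path)
})
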