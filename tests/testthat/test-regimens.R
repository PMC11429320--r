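test_that("standard IV regimen lays out induction and q8w maintenance", {
  reg <- iv_standard(70, 5, 54)
  expect_equal(reg$events$time / 168, c(0, 2, 6, 14, 22, 30, 38, 46, 54))
  expect_true(all(reg$events$amount == 350))
  expect_true(all(reg$events$duration == 2))

  expect_equal(unique(iv_standard(60, 5, 30)$events$amount), 300)
  expect_equal(nrow(iv_standard(70, 5, 6)$events), 3)  # induction only
})

test_that("SC switch regimen mixes IV induction with q2w SC dosing", {
  reg <- sc_switch(70, 120, horizon_weeks = 30)
  iv <- reg$events[reg$events$route == "iv_infusion", ]
  sc <- reg$events[reg$events$route == "sc", ]
  expect_equal(nrow(iv), 2)
  expect_equal(unique(iv$amount), 350)
  expect_equal(nrow(sc), 13)                 # weeks 6, 8, ..., 30
  expect_equal(sc$time / 168, seq(6, 30, by = 2))
  expect_equal(unique(sc$amount), 120)

  heavy <- sc_switch(120, 240, horizon_weeks = 30)
  expect_equal(unique(heavy$events$amount[heavy$events$route ==
                                            "iv_infusion"]), 600)
  expect_equal(unique(heavy$events$amount[heavy$events$route == "sc"]), 240)
})

test_that("event times are exact multiples of one week over 54 weeks", {
  reg <- sc_switch(70, 120, horizon_weeks = 54)
  expect_true(all(reg$events$time %% 168 == 0))
  reg2 <- iv_standard(70, 5, 54)
  expect_identical(reg2$events$time, reg2$events$time %/% 168 * 168)
})

test_that("regimen construction rejects invalid layouts", {
  expect_error(iv_standard(70, 5, 4), "horizon")
  expect_error(sc_switch(70, 120, switch_week = 1, horizon_weeks = 30),
               "switch_week")
  expect_error(regimen(data.frame(time = 0, route = "sc", amount = -1,
                                  duration = NA), 168), "positive")
  expect_error(regimen(data.frame(time = 0, route = "iv_infusion",
                                  amount = 100, duration = NA), 168),
               "duration")
})
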