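test_that("leakage flow matches the hand-evaluated stack/wind form", {
  # sqrt(1.5e-4 * 20 + 1e-4 * 16) * 0.05 m^3/s = 12.21 m^3/h
  expect_equal(leakage_flow(0.05, k_s = 1.5e-4, k_w = 1.0e-4,
                            t_in = 20, t_out = 0, wind = 4),
               12.2082, tolerance = 1e-4)
  expect_equal(leakage_flow(0.05, 1.5e-4, 1e-4, t_in = 15, t_out = 15,
                            wind = 0), 0)
  # monotone nondecreasing in |dT| and wind
  dts <- seq(0, 30, by = 5)
  q1 <- leakage_flow(0.05, 1.5e-4, 1e-4, t_in = 20, t_out = 20 - dts, wind = 2)
  expect_true(all(diff(q1) >= 0))
  ws <- seq(0, 10, by = 1)
  q2 <- leakage_flow(0.05, 1.5e-4, 1e-4, t_in = 20, t_out = 10, wind = ws)
  expect_true(all(diff(q2) >= 0))
})

test_that("total airflow combines components in quadrature", {
  expect_equal(total_flow(3, 4, 0), 5)
  expect_equal(total_flow(7, 0, 0), 7)
  expect_equal(total_flow(1, 1, 1), sqrt(3))
  expect_error(total_flow(-1, 0, 0), ">= 0")
  # dominates each of its arguments
  set.seed(4)
  q <- matrix(runif(30, 0, 500), ncol = 3)
  tf <- total_flow(q[, 1], q[, 2], q[, 3])
  expect_true(all(tf >= apply(q, 1, max)))
})

test_that("hourly AER responds to building operation as expected", {
  home <- home_model("h1", a_leak = 0.06, volume = 300, fan_flow = 300,
                     openable_area = 1)
  quest <- tibble::tibble(date = day1, t_in = 21, windows_open = FALSE,
                          doors_open = FALSE, fan_on = FALSE)
  # no driving force, closed house: AER = 0
  wx0 <- const_weather(day1, t_out = 21, wind = 0)
  aer0 <- hourly_aer(wx0, home, quest)
  expect_equal(nrow(aer0), 24L)
  expect_equal(aer0$aer, rep(0, 24))
  # fan alone: AER = fan_flow / volume
  quest_fan <- dplyr::mutate(quest, fan_on = TRUE)
  aer_fan <- hourly_aer(wx0, home, quest_fan)
  expect_equal(aer_fan$aer, rep(1, 24))
  # opening windows never decreases AER under identical weather
  wx <- const_weather(day1, t_out = 8, wind = 3)
  closed <- hourly_aer(wx, home, quest)$aer
  open <- hourly_aer(wx, home, dplyr::mutate(quest, windows_open = TRUE))$aer
  expect_true(all(open >= closed))
  expect_true(all(closed > 0))
})

test_that("missing weather hours are reported by timestamp", {
  home <- home_model("h1", a_leak = 0.06, volume = 300)
  quest <- tibble::tibble(date = day1, t_in = 21, windows_open = FALSE,
                          doors_open = FALSE, fan_on = FALSE)
  wx <- const_weather(day1)[-c(3, 4), ]
  expect_error(hourly_aer(wx, home, quest), "missing hour")
})

test_that("AER scales inversely with volume for fixed flows", {
  quest <- tibble::tibble(date = day1, t_in = 21, windows_open = FALSE,
                          doors_open = FALSE, fan_on = FALSE)
  wx <- const_weather(day1, t_out = 5, wind = 4)
  h1 <- home_model("h1", a_leak = 0.06, volume = 300)
  h2 <- home_model("h2", a_leak = 0.06, volume = 600)
  a1 <- hourly_aer(wx, h1, quest)$aer
  a2 <- hourly_aer(wx, h2, quest)$aer
  expect_equal(a1, 2 * a2)
})

test_that("stack and wind coefficient lookups are valid and ordered", {
  expect_true(all(diff(stack_coefficient(1:3)) > 0))
  expect_true(all(diff(wind_coefficient(1:5)) < 0))
  expect_error(stack_coefficient(4), "1, 2 or 3")
  expect_error(wind_coefficient(0), "1..5")
})
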