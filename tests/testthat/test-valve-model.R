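# Sigmoid evaluation, pressure-map and sigmoid fitting, flow prediction,
# opening threshold, R^2.

test_that("eval_valve_resistance has the right value, limits and bounds", {
  m <- valve_resistance_model(0.1, 100, 20)
  expect_equal(eval_valve_resistance(m, 0), 0.1 + 100 / 2)
  # large-argument limits without overflow (s * dp ~ +-800)
  expect_equal(eval_valve_resistance(m, 40), 0.1, tolerance = 1e-12)
  expect_equal(eval_valve_resistance(m, -40), 100.1, tolerance = 1e-12)

  # strictly decreasing and bounded in (r_vl, r_vl + r_vh); range kept
  # where the logistic tails stay resolvable in double precision
  dp <- seq(-1.4, 1.4, by = 0.05)
  v <- eval_valve_resistance(m, dp)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > m$r_vl & v < m$r_vl + m$r_vh))

  expect_error(valve_resistance_model(-0.1, 100, 20), class = "invalid_model")
})

test_that("valve_opening_threshold matches the closed form and its oracle", {
  td1 <- valve_resistance_model(0.088, 1.54e4, 25.4)
  thr1 <- valve_opening_threshold(td1)
  expect_equal(round(thr1, 3), 0.593)

  # at the threshold the resistance sits within 5% of the open plateau
  expect_lt(abs(eval_valve_resistance(td1, thr1) - td1$r_vl), 0.05 * td1$r_vl * 1.01)

  # 1/s scaling
  td1_fast <- valve_resistance_model(0.088, 1.54e4, 2 * 25.4)
  expect_equal(valve_opening_threshold(td1_fast), thr1 / 2)

  # closed form vs numeric inversion of the sigmoid at 1.05 r_vl, all five
  # published parameter sets
  for (m in table1_models()) {
    expect_lt(abs(valve_opening_threshold(m) - threshold_by_bisection(m)), 1e-4)
  }
})

test_that("threshold_summary reproduces the published mean and spread", {
  thr <- vapply(table1_models(), valve_opening_threshold, numeric(1))
  ts <- threshold_summary(unname(thr))
  expect_equal(round(ts$mean, 2), 0.84)
  expect_equal(round(ts$sd, 2), 0.42)

  one <- threshold_summary(thr[1])
  expect_equal(one$sd, 0)
  rep5 <- threshold_summary(rep(thr[1], 5))
  expect_equal(rep5$sd, 0)
  expect_equal(rep5$mean, unname(thr[1]))
  expect_error(threshold_summary(list()), class = "empty_input")
})

test_that("fit_pressure_map recovers exponentials and degenerate data", {
  dp <- 1:10
  pm <- fit_pressure_map(dp, 0.5 * exp(0.2 * dp))
  expect_equal(pm$p0, 0.5, tolerance = 1e-6)
  expect_equal(pm$a, 0.2, tolerance = 1e-6)
  expect_equal(eval_pressure_map(pm, 0), pm$p0)

  pm_const <- fit_pressure_map(dp, rep(0.7, 10))
  expect_equal(pm_const$p0, 0.7, tolerance = 1e-4)
  expect_equal(pm_const$a, 0, tolerance = 1e-4)

  expect_warning(pm_drop <- fit_pressure_map(0:10, c(-1, 0.5 * exp(0.2 * (1:10)))),
                 "non-positive")
  expect_equal(pm_drop$a, 0.2, tolerance = 1e-6)
  expect_error(suppressWarnings(fit_pressure_map(1:3, c(-1, -2, 0.5))),
               class = "insufficient_data")
})

test_that("fit_valve_model recovers known parameters from clean data", {
  truth <- valve_resistance_model(0.088, 1.54e4, 25.4)
  dp <- seq(0.05, 2, length.out = 15)  # spans the transition (thr ~ 0.59)
  r <- eval_valve_resistance(truth, dp)
  fit <- fit_valve_model(dp, r)
  expect_equal(fit$model$r_vl, truth$r_vl, tolerance = 1e-2)
  expect_equal(fit$model$r_vh, truth$r_vh, tolerance = 1e-2)
  expect_equal(fit$model$s, truth$s, tolerance = 1e-2)
  expect_gte(fit$r_squared_resistance, 0.999)
  expect_equal(fit$r_squared_resistance, 1, tolerance = 1e-9)
})

test_that("fit_valve_model identifies a plateau and rejects tiny inputs", {
  dp <- seq(1, 5, length.out = 8)
  fit <- fit_valve_model(dp, rep(0.25, 8) + c(1e-6, rep(0, 7)))
  expect_equal(fit$model$r_vl, 0.25, tolerance = 1e-3)
  expect_error(fit_valve_model(c(1, 2), c(1, 2)), class = "insufficient_data")
})

test_that("log-residual objective handles huge r_vh spans", {
  truth <- valve_resistance_model(0.085, 6.42e10, 85.8)
  dp <- seq(0.05, 1, length.out = 12)
  r <- eval_valve_resistance(truth, dp)
  fit <- fit_valve_model(dp, r, objective = "log")
  expect_equal(fit$model$r_vl, truth$r_vl, tolerance = 1e-2)
  expect_equal(log10(fit$model$r_vh), log10(truth$r_vh), tolerance = 0.05)
})

test_that("predict_flow matches closed forms and the forward solver", {
  # dp = 0 gives zero flow
  m <- valve_resistance_model(0.1, 10, 20)
  pm <- exponential_pressure_model(0.5, 0.1)
  expect_equal(predict_flow(0, m, pm, r_conn = 0.4, r_vessel = 0.01), 0)

  # r_vh -> 0: constant valve resistance, linear circuit
  m_const <- valve_resistance_model(0.1, 1e-14, 20)
  q <- predict_flow(c(1, 5, 10), m_const, pm, r_conn = 0.4, r_vessel = rep(0.01, 3))
  expect_equal(q, c(1, 5, 10) / (0.4 + 0.01 + 0.1), tolerance = 1e-12)

  # round trip against the self-consistent forward solver: with the true
  # sigmoid evaluated at the true valve gradients, predicted flow matches
  # the generated flow at every step to well under 0.1%
  truth <- make_truth(table1_models()$TD1, seed = 2L)
  series <- generate_segment_series(truth)
  rs <- decompose_resistance(series, truth$r_conn, default_fluid())
  q_pred <- predict_flow(rs$dp_total, truth$valve, r_conn = truth$r_conn,
                         r_vessel = rs$r_vessel, dp_valve = rs$dp_valve)
  expect_equal(q_pred, rs$flow, tolerance = 1e-3)

  expect_error(predict_flow(1, m, NULL, r_conn = 0.4, r_vessel = 0.01),
               class = "invalid_model")
})

test_that("coefficient_of_determination follows its definition", {
  expect_equal(coefficient_of_determination(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(coefficient_of_determination(rep(2, 3), c(1, 2, 3)), 0)
  expect_equal(coefficient_of_determination(c(1, 2, 4), c(1, 2, 3)), 0.5)
  # worse than the mean -> negative, reported as computed
  expect_lt(coefficient_of_determination(c(3, 2, 1), c(1, 2, 3)), 0)
  expect_error(coefficient_of_determination(c(1, 2), c(2, 2)),
               class = "undefined_r_squared")
})
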