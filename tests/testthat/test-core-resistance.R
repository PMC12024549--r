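# Poiseuille physics, unit conversions, and the per-step resistance
# decomposition.

test_that("poiseuille_resistance reproduces the phantom value and scaling laws", {
  r_phantom <- poiseuille_resistance(default_fluid(), phantom_tube())
  expect_equal(signif(r_phantom, 3), 1.86e-3)

  # D^4 scaling: doubling the diameter divides the resistance by 16
  r_double <- poiseuille_resistance(default_fluid(), tube_geometry(31, 6))
  expect_equal(r_double, r_phantom / 16, tolerance = 1e-12)

  # independent SI-only hand computation as oracle
  mu <- 1 * 1e-3; L <- 1000 * 1e-3; D <- 1 * 1e-3
  r_si <- 128 * mu * L / (pi * D^4)
  r_bench_oracle <- r_si * (1e-6 / 60) / 98.0665
  expect_equal(poiseuille_resistance(fluid_properties(1), tube_geometry(1000, 1)),
               r_bench_oracle, tolerance = 1e-12)
})

test_that("poiseuille_resistance is monotone in its arguments", {
  base <- poiseuille_resistance(default_fluid(), tube_geometry(31, 3))
  for (f in c(1.1, 2, 5)) {
    expect_lt(poiseuille_resistance(default_fluid(), tube_geometry(31, 3 * f)), base)
    expect_gt(poiseuille_resistance(default_fluid(), tube_geometry(31 * f, 3)), base)
    expect_gt(poiseuille_resistance(fluid_properties(0.7 * f), tube_geometry(31, 3)), base)
  }
  expect_error(tube_geometry(31, -1), class = "invalid_geometry")
  expect_error(fluid_properties(0), class = "invalid_fluid")
})

test_that("resistance unit round-trip is exact to 1e-12 relative", {
  for (r in c(1.86e-3, 0.393, 2, 1.54e4, 6.42e10)) {
    expect_equal(resistance_from_si(resistance_to_si(r)), r, tolerance = 1e-12)
  }
})

test_that("total_resistance follows dp/Q and rejects zero flow", {
  expect_equal(total_resistance(10, 5), 2)
  expect_equal(total_resistance(c(1, 2), c(2, 2)), c(0.5, 1))
  expect_error(total_resistance(0, 0), class = "undefined_resistance")
})

test_that("inner_diameter applies the chosen wall convention", {
  expect_equal(inner_diameter(1.00, 0.11), 0.89)
  expect_equal(inner_diameter(1.00, 0.11, convention = "geometric"), 0.78)
  expect_equal(inner_diameter(2.5, 1e-12), 2.5, tolerance = 1e-9)
  expect_error(inner_diameter(0.10, 0.11), class = "invalid_measurement")
})

test_that("decompose_resistance subtracts series resistances step by step", {
  seg <- segment_spec("T", 31, wall_thickness = 0.11)
  fluid <- default_fluid()
  series <- bench_series(seg, dp_total = c(0, 2, 4), flow = c(0, 1, 2.5),
                         d_out = c(1.8, 2.0, 2.2))
  rs <- decompose_resistance(series, r_conn = 0.393, fluid)

  # zero-flow step dropped
  expect_equal(nrow(rs), 2L)
  expect_equal(rs$dp_total, c(2, 4))

  # r_valve by subtraction, against values computed independently here
  r_vessel_2 <- poiseuille_resistance(fluid, tube_geometry(seg$mounted_length, 2.0 - 0.11))
  expect_equal(rs$r_total[1], 2 / 1)
  expect_equal(rs$r_valve[1], 2 / 1 - (0.393 + r_vessel_2))
  expect_equal(rs$dp_valve[1], 2 - (0.393 + r_vessel_2) * 1)

  # spec'd arithmetic: r_total 2.000, r_conn 0.393, r_vessel 0.010 -> r_valve 1.597
  expect_equal(2.000 - (0.393 + 0.010), 1.597)
})

test_that("pressure decomposition conserves dp_total to machine precision", {
  for (m in table1_models()[c("TD1", "TD5")]) {
    truth <- make_truth(m, seed = 3L)
    series <- generate_segment_series(truth)
    rs <- decompose_resistance(series, truth$r_conn, default_fluid())
    expect_lt(max(abs(rs$dp_conn + rs$dp_vessel + rs$dp_valve - rs$dp_total)),
              .Machine$double.eps * 64)
    expect_equal(rs$r_total, rs$r_conn + rs$r_vessel + rs$r_valve, tolerance = 1e-14)
  }
})

test_that("decompose_resistance inverts the noiseless forward solver", {
  for (nm in names(table1_models())) {
    m <- table1_models()[[nm]]
    truth <- make_truth(m, seed = 11L)
    series <- generate_segment_series(truth)
    rs <- decompose_resistance(series, truth$r_conn, default_fluid())
    # recovered per-step valve resistance equals the true sigmoid at the
    # recovered valve gradient
    expect_equal(rs$r_valve, eval_valve_resistance(m, rs$dp_valve),
                 tolerance = 1e-9)
  }
})

test_that("negative valve resistance warns but is kept", {
  seg <- segment_spec("T", 31, wall_thickness = 0.11)
  series <- bench_series(seg, dp_total = c(1, 2), flow = c(10, 20),
                         d_out = c(2, 2))
  expect_warning(rs <- decompose_resistance(series, r_conn = 0.393),
                 "negative valve resistance")
  expect_true(all(rs$r_valve < 0))

  all_zero <- bench_series(seg, dp_total = c(0, 1), flow = c(0, 0), d_out = c(2, 2))
  expect_error(decompose_resistance(all_zero, 0.393), class = "empty_series")
})
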