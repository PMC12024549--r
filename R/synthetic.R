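# Synthetic bench-data generator with known ground truth.
#
# Emulates the ex vivo perfusion protocol: a pressure reservoir applies a
# staircase of total gradients (0-10 cmH2O in 1-cmH2O steps by default); at
# each step the segment's outer diameter follows a saturating
# diameter-pressure law and the steady flow is the self-consistent solution
# of the series-resistance circuit
#
#   dp_total = (R_conn + R_vessel(D) + R_valve(dp_valve)) * Q,
#   dp_valve = dp_total - (R_conn + R_vessel) * Q,
#
# where R_valve is the ground-truth sigmoid. Measurement noise is
# multiplicative Gaussian on flow and diameter. The generator is the test
# oracle for the whole pipeline: with zero noise, decomposition and fitting
# must recover the ground truth.

#' Pressure grid for a synthetic bench run
#'
#' @param values applied total pressure gradients, cmH2O; default the bench
#'   staircase 0-10 cmH2O in 1-cmH2O increments
#' @return an object of class `pressure_grid`
#' @export
pressure_grid <- function(values = 0:10) {
  if (any(values < 0) || any(diff(values) <= 0)) {
    stop_df("pressure grid must be non-negative and strictly increasing",
            "invalid_grid")
  }
  structure(list(values = as.numeric(values)), class = "pressure_grid")
}

#' Ground truth for a synthetic bench segment
#'
#' @param valve a [valve_resistance_model()] — the true valve sigmoid
#' @param r_conn true connector resistance, cmH2O.min/mL
#' @param segment a [segment_spec()]
#' @param fluid a [fluid_properties()]
#' @param d_min,d_max,p_half outer-diameter law parameters: the diameter
#'   rises from `d_min` (mm, at zero pressure) towards `d_max` (mm) with
#'   half-saturation at `p_half` (cmH2O) — a rectangular hyperbola that
#'   reproduces the observed rapid distension followed by a plateau as the
#'   wall stiffens
#' @param noise_flow,noise_diameter relative standard deviations of the
#'   multiplicative Gaussian measurement noise (defaults 2% and 1%)
#' @param seed integer seed driving all noise draws
#' @return an object of class `synthetic_ground_truth`
#' @export
synthetic_ground_truth <- function(valve,
                                   r_conn = 0.393,
                                   segment = segment_spec("SYN", 31),
                                   fluid = fluid_properties(0.7),
                                   d_min = 1.5, d_max = 3.5, p_half = 2,
                                   noise_flow = 0.02, noise_diameter = 0.01,
                                   seed = 1L) {
  stopifnot(inherits(valve, "valve_resistance_model"),
            inherits(segment, "segment_spec"),
            inherits(fluid, "fluid_properties"))
  if (!(d_max > d_min && d_min > segment$wall_thickness)) {
    stop_df("need d_max > d_min > wall thickness", "invalid_truth")
  }
  if (p_half <= 0 || noise_flow < 0 || noise_diameter < 0) {
    stop_df("p_half must be positive, noise levels non-negative", "invalid_truth")
  }
  structure(list(valve = valve, r_conn = r_conn, segment = segment,
                 fluid = fluid, d_min = d_min, d_max = d_max, p_half = p_half,
                 noise_flow = noise_flow, noise_diameter = noise_diameter,
                 seed = as.integer(seed)),
            class = "synthetic_ground_truth")
}

#' Saturating outer-diameter law
#'
#' `d_min + (d_max - d_min) * dp / (dp + p_half)`: strictly increasing in
#' pressure, `d_min` at zero and saturating towards `d_max`.
#'
#' @param truth a [synthetic_ground_truth()]
#' @param dp_total applied pressure gradient, cmH2O (vectorised, >= 0)
#' @return outer diameter, mm
#' @export
diameter_at_pressure <- function(truth, dp_total) {
  stopifnot(inherits(truth, "synthetic_ground_truth"), all(dp_total >= 0))
  truth$d_min + (truth$d_max - truth$d_min) * dp_total / (dp_total + truth$p_half)
}

# vessel Poiseuille resistance at the step's (noise-free) diameter,
# using the same inner-diameter convention as the analysis (D = Dout - t)
truth_vessel_resistance <- function(truth, d_out) {
  d_in <- inner_diameter(d_out, truth$segment$wall_thickness)
  poiseuille_resistance(truth$fluid,
                        tube_geometry(truth$segment$mounted_length, d_in))
}

#' Self-consistent steady flow at one pressure step
#'
#' Solves the implicit circuit equation for Q by bisection. The residual
#' `Q (R_conn + R_vessel + R_valve(dp_valve(Q))) - dp_total` is strictly
#' increasing in Q (the valve gradient falls as Q rises, so valve
#' resistance rises), which guarantees a bracket on
#' `[0, dp_total / (R_conn + R_vessel + r_vl)]`; iteration stops when the
#' absolute pressure residual is at most 1e-10 cmH2O.
#'
#' @param truth a [synthetic_ground_truth()]
#' @param dp_total applied pressure gradient, cmH2O (scalar, >= 0)
#' @return a list with the consistent `flow` (mL/min), `dp_valve` (cmH2O),
#'   and the step's `r_vessel`, `r_valve`, `d_out`
#' @export
solve_steady_flow <- function(truth, dp_total) {
  stopifnot(inherits(truth, "synthetic_ground_truth"),
            length(dp_total) == 1L, dp_total >= 0)
  d_out <- diameter_at_pressure(truth, dp_total)
  r_vessel <- truth_vessel_resistance(truth, d_out)
  if (dp_total == 0) {
    return(list(flow = 0, dp_valve = 0, r_vessel = r_vessel,
                r_valve = eval_valve_resistance(truth$valve, 0), d_out = d_out))
  }
  r_ser <- truth$r_conn + r_vessel
  resid <- function(q) {
    dpv <- dp_total - r_ser * q
    q * (r_ser + eval_valve_resistance(truth$valve, dpv)) - dp_total
  }
  lo <- 0
  hi <- dp_total / (r_ser + truth$valve$r_vl)
  if (resid(hi) < -1e-10) {
    stop_df("bisection bracket failed; inconsistent ground truth", "internal_error")
  }
  q <- hi
  for (i in 1:200) {
    q <- (lo + hi) / 2
    r <- resid(q)
    if (abs(r) <= 1e-10) break
    if (r > 0) hi <- q else lo <- q
  }
  dpv <- dp_total - r_ser * q
  list(flow = q, dp_valve = dpv, r_vessel = r_vessel,
       r_valve = eval_valve_resistance(truth$valve, dpv), d_out = d_out)
}

# one multiplicative-noise draw with redraws on non-physical values
noisy <- function(value, rel_sd, lower) {
  if (rel_sd == 0) return(value)
  for (i in 1:100) {
    v <- value * (1 + stats::rnorm(1L, sd = rel_sd))
    if (v > lower) return(v)
  }
  stop_df("100 consecutive noise draws produced non-physical values",
          "noise_redraw_exhausted")
}

#' Generate a synthetic bench series for one segment
#'
#' Per pressure step, evaluates the diameter law and the self-consistent
#' flow, then applies independent multiplicative Gaussian noise to the
#' recorded flow and outer diameter (the underlying physics always uses
#' the noise-free diameter). The zero-pressure step records exactly zero
#' flow. All draws come from `truth$seed`; equal configurations generate
#' bit-identical series.
#'
#' @param truth a [synthetic_ground_truth()]
#' @param grid a [pressure_grid()]
#' @return a [bench_series()]
#' @export
generate_segment_series <- function(truth, grid = pressure_grid()) {
  stopifnot(inherits(truth, "synthetic_ground_truth"),
            inherits(grid, "pressure_grid"))
  dp <- grid$values
  sol <- lapply(dp, function(p) solve_steady_flow(truth, p))
  flow_true <- vapply(sol, `[[`, numeric(1), "flow")
  dout_true <- vapply(sol, `[[`, numeric(1), "d_out")
  t_wall <- truth$segment$wall_thickness
  series <- with_preserved_rng(truth$seed, {
    flow <- vapply(seq_along(dp), function(i) {
      if (dp[i] == 0) 0 else noisy(flow_true[i], truth$noise_flow, lower = 0)
    }, numeric(1))
    d_out <- vapply(dout_true, noisy, numeric(1),
                    rel_sd = truth$noise_diameter, lower = t_wall)
    list(flow = flow, d_out = d_out)
  })
  bench_series(truth$segment, dp, series$flow, series$d_out)
}

#' Generate a synthetic phantom calibration series
#'
#' The phantom circuit is linear: `Q = dp / (r_conn + R_phantom)`, plus
#' seeded multiplicative flow noise (zero flow at zero pressure is exact).
#'
#' @param r_conn true connector resistance, cmH2O.min/mL
#' @param tube the phantom [tube_geometry()]
#' @param fluid a [fluid_properties()]
#' @param grid a [pressure_grid()]
#' @param noise relative sd of multiplicative flow noise
#' @param seed integer seed
#' @return a [phantom_experiment()]
#' @export
generate_phantom_series <- function(r_conn = 0.393,
                                    tube = tube_geometry(31, 3),
                                    fluid = fluid_properties(0.7),
                                    grid = pressure_grid(),
                                    noise = 0, seed = 1L) {
  r_total <- r_conn + poiseuille_resistance(fluid, tube)
  dp <- grid$values
  flow_true <- dp / r_total
  flow <- with_preserved_rng(seed, {
    vapply(seq_along(dp), function(i) {
      if (dp[i] == 0) 0 else noisy(flow_true[i], noise, lower = 0)
    }, numeric(1))
  })
  phantom_experiment(dp, flow, tube)
}
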