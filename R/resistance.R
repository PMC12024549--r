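# Poiseuille physics and the per-step decomposition of measured total
# resistance into connector, vessel and valve contributions.

#' Poiseuille hydraulic resistance of a circular tube
#'
#' Computes `R = 128 mu L / (pi D^4)` for laminar fully developed flow and
#' returns it in bench units. The computation itself runs in SI and the
#' result is converted with 1 cmH2O = 98.0665 Pa, 1 cP = 1e-3 Pa.s,
#' 1 mL/min = 1e-6/60 m^3/s.
#'
#' @param fluid a [fluid_properties()]
#' @param tube a [tube_geometry()]
#' @return hydraulic resistance in cmH2O.min/mL
#' @examples
#' # resistance of the rigid calibration phantom (3 mm lumen, 31 mm long)
#' poiseuille_resistance(fluid_properties(0.7), tube_geometry(31, 3))
#' @export
poiseuille_resistance <- function(fluid, tube) {
  stopifnot(inherits(fluid, "fluid_properties"), inherits(tube, "tube_geometry"))
  mu_si <- fluid$viscosity * df_units$cP_PaS    # Pa.s
  l_si  <- tube$length * 1e-3                   # m
  d_si  <- tube$inner_diameter * 1e-3           # m
  r_si  <- 128 * mu_si * l_si / (pi * d_si^4)   # Pa.s/m^3
  resistance_from_si(r_si)
}

#' Total hydraulic resistance from a pressure/flow measurement
#'
#' `R_total = dp_total / Q`. Undefined at zero flow; the 0-cmH2O pressure
#' step (where the flow is also zero) must be excluded by the caller.
#'
#' @param dp_total total pressure gradient, cmH2O (vectorised)
#' @param flow volumetric flow rate, mL/min, strictly positive
#' @return resistance in cmH2O.min/mL
#' @export
total_resistance <- function(dp_total, flow) {
  if (any(!is.finite(flow)) || any(flow <= 0)) {
    stop_df("total resistance is undefined at zero flow; drop zero-flow steps",
            "undefined_resistance")
  }
  dp_total / flow
}

#' Inner diameter from outer diameter and wall thickness
#'
#' The default convention is `D = D_out - t`, taking the histology-derived
#' thickness as the single correction applied to the imaged outer diameter.
#' `convention = "geometric"` applies the circular-annulus relation
#' `D = D_out - 2 t` instead.
#'
#' @param d_out outer diameter, mm (vectorised)
#' @param wall_thickness wall thickness t, mm
#' @param convention `"as-printed"` (default, `D_out - t`) or `"geometric"`
#'   (`D_out - 2 t`)
#' @return inner diameter in mm
#' @export
inner_diameter <- function(d_out, wall_thickness,
                           convention = c("as-printed", "geometric")) {
  convention <- match.arg(convention)
  k <- if (convention == "geometric") 2 else 1
  d <- d_out - k * wall_thickness
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop_df("outer diameter does not exceed the wall correction", "invalid_measurement")
  }
  d
}

#' Decompose measured resistance into connector, vessel and valve parts
#'
#' For every pressure step with non-zero flow, computes the inner diameter,
#' the vessel Poiseuille resistance at the mounted length, the total
#' resistance `dp_total / Q`, the valve resistance by subtraction
#' `R_valve = R_total - (R_conn + R_vessel)`, and the pressure drops across
#' each element (`dp_valve = dp_total - (R_conn + R_vessel) Q`). Zero-flow
#' steps are dropped. Negative computed valve resistances are kept in the
#' output but flagged with a warning so downstream fits see the raw data.
#'
#' @param series a [bench_series()]
#' @param r_conn connector resistance from phantom calibration, cmH2O.min/mL
#' @param fluid a [fluid_properties()]
#' @param convention inner-diameter convention, see [inner_diameter()]
#' @return a data.frame of class `resistance_series` with columns
#'   `dp_total`, `flow`, `inner_diameter`, `r_total`, `r_conn`, `r_vessel`,
#'   `r_valve`, `dp_conn`, `dp_vessel`, `dp_valve`
#' @export
decompose_resistance <- function(series, r_conn, fluid = fluid_properties(),
                                 convention = c("as-printed", "geometric")) {
  stopifnot(inherits(series, "bench_series"), r_conn >= 0)
  convention <- match.arg(convention)
  keep <- series$flow > 0
  if (!any(keep)) {
    stop_df("all pressure steps have zero flow; nothing to decompose",
            "empty_series")
  }
  dp <- series$dp_total[keep]
  q  <- series$flow[keep]
  d_in <- inner_diameter(series$d_out[keep], series$segment$wall_thickness,
                         convention)
  r_vessel <- vapply(d_in, function(d) {
    poiseuille_resistance(fluid, tube_geometry(series$segment$mounted_length, d))
  }, numeric(1))
  r_total <- total_resistance(dp, q)
  r_valve <- r_total - (r_conn + r_vessel)
  dp_conn   <- r_conn * q
  dp_vessel <- r_vessel * q
  dp_valve  <- dp - (r_conn + r_vessel) * q
  if (any(r_valve < 0)) {
    warning(sprintf(
      "negative valve resistance at %d step(s) (dp_total = %s cmH2O); kept as computed",
      sum(r_valve < 0), paste(dp[r_valve < 0], collapse = ", ")))
  }
  out <- data.frame(dp_total = dp, flow = q, inner_diameter = d_in,
                    r_total = r_total, r_conn = r_conn, r_vessel = r_vessel,
                    r_valve = r_valve, dp_conn = dp_conn,
                    dp_vessel = dp_vessel, dp_valve = dp_valve)
  attr(out, "segment_id") <- series$segment$segment_id
  class(out) <- c("resistance_series", "data.frame")
  out
}
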