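# Connector-resistance calibration against a rigid phantom tube.
#
# Everything between the pressure reservoir and the mounted specimen
# (cannulae, tubing, fittings) is rigid, so its resistance R_conn is one
# constant shared by all segment analyses. It is isolated by flowing the
# bench fluid through a phantom tube of known geometry: the slope of the
# linear pressure-flow relation is the total setup resistance, and the
# phantom's own Poiseuille resistance is subtracted from it.

#' Phantom calibration experiment
#'
#' @param tube a [tube_geometry()] for the rigid phantom
#'   (defaults: 3 mm lumen, 31 mm long)
#' @param dp_total applied total pressure gradients, cmH2O, strictly increasing
#' @param flow measured flow rates, mL/min
#' @return an object of class `phantom_experiment`
#' @export
phantom_experiment <- function(dp_total, flow, tube = tube_geometry(31, 3)) {
  stopifnot(inherits(tube, "tube_geometry"))
  n <- length(dp_total)
  if (n < 2L || length(flow) != n) {
    stop_df("dp_total and flow must have equal length >= 2", "invalid_series")
  }
  if (any(diff(dp_total) <= 0)) {
    stop_df("dp_total must be strictly increasing", "invalid_series")
  }
  structure(list(tube = tube, dp_total = dp_total, flow = flow),
            class = "phantom_experiment")
}

#' Linear pressure-flow fit of the phantom experiment
#'
#' Ordinary least squares of pressure gradient against flow. The slope is
#' the total hydraulic resistance of the phantom setup; the intercept is a
#' free diagnostic (it should be near zero) and is not used downstream.
#' The zero-pressure/zero-flow point is a legitimate observation here and
#' is included.
#'
#' @param exp a [phantom_experiment()]
#' @return a list with `slope` (cmH2O.min/mL), `intercept` (cmH2O) and
#'   `r_squared_linear`
#' @export
fit_phantom_line <- function(exp) {
  stopifnot(inherits(exp, "phantom_experiment"))
  if (diff(range(exp$flow)) == 0) {
    stop_df("all flows identical; linear fit is singular", "singular_fit")
  }
  fit <- stats::lm(dp ~ q, data = data.frame(dp = exp$dp_total, q = exp$flow))
  co <- stats::coef(fit)
  # R^2 computed directly (summary.lm warns on exact lines)
  ss_tot <- sum((exp$dp_total - mean(exp$dp_total))^2)
  list(slope = unname(co[["q"]]),
       intercept = unname(co[["(Intercept)"]]),
       r_squared_linear = 1 - sum(stats::residuals(fit)^2) / ss_tot)
}

#' Connector resistance from the phantom slope
#'
#' Subtracts the phantom's Poiseuille resistance from the fitted slope:
#' `R_conn = slope - R_phantom`. A negative result means the measured setup
#' resistance is below the phantom's own theoretical resistance, which is
#' physically impossible and reported as an error.
#'
#' @param slope phantom-setup slope, cmH2O.min/mL
#' @param fluid a [fluid_properties()]
#' @param tube the phantom [tube_geometry()]
#' @param intercept,r_squared_linear optional diagnostics from
#'   [fit_phantom_line()], carried through into the result
#' @return an object of class `connector_calibration` with fields `slope`,
#'   `intercept`, `r_squared_linear`, `r_phantom`, `r_conn`
#' @export
connector_resistance <- function(slope, fluid = fluid_properties(),
                                 tube = tube_geometry(31, 3),
                                 intercept = NA_real_,
                                 r_squared_linear = NA_real_) {
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0) {
    stop_df("slope must be a single positive resistance", "invalid_calibration")
  }
  r_phantom <- poiseuille_resistance(fluid, tube)
  r_conn <- slope - r_phantom
  if (r_conn < 0) {
    stop_df(sprintf(
      "calibration inconsistent: slope %.4g below phantom Poiseuille resistance %.4g",
      slope, r_phantom), "calibration_inconsistent")
  }
  structure(list(slope = slope, intercept = intercept,
                 r_squared_linear = r_squared_linear,
                 r_phantom = r_phantom, r_conn = r_conn),
            class = "connector_calibration")
}

#' Run the full phantom calibration
#'
#' Convenience wrapper: linear fit then Poiseuille subtraction.
#'
#' @inheritParams fit_phantom_line
#' @param fluid a [fluid_properties()]
#' @return a `connector_calibration`
#' @export
calibrate_connector <- function(exp, fluid = fluid_properties()) {
  line <- fit_phantom_line(exp)
  connector_resistance(line$slope, fluid, exp$tube,
                       intercept = line$intercept,
                       r_squared_linear = line$r_squared_linear)
}

#' @export
print.connector_calibration <- function(x, ...) {
  cat(sprintf(paste0(
    "<connector_calibration>\n",
    "  slope (setup R_total): %.6g cmH2O.min/mL (intercept %.3g, linear R^2 %.4f)\n",
    "  R_phantom:             %.6g cmH2O.min/mL\n",
    "  R_conn:                %.6g cmH2O.min/mL\n"),
    x$slope, x$intercept, x$r_squared_linear, x$r_phantom, x$r_conn))
  invisible(x)
}
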