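# Domain types for the bench analysis, as lightweight validated S3 records.

stop_df <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ductflow_error")))
}

#' Fluid properties
#'
#' @param viscosity dynamic viscosity in centipoise (cP). The bench fluid is
#'   0.9% saline at 0.7 cP; lymph itself is close to 1 cP.
#' @return an object of class `fluid_properties`
#' @export
fluid_properties <- function(viscosity = 0.7) {
  if (!is.numeric(viscosity) || length(viscosity) != 1L || !is.finite(viscosity) ||
      viscosity <= 0) {
    stop_df("viscosity must be a single positive number (cP)", "invalid_fluid")
  }
  structure(list(viscosity = viscosity), class = "fluid_properties")
}

#' Tube geometry
#'
#' A straight circular tube characterised by its length and inner diameter,
#' both in mm. `fully_developed` records whether the length exceeds five
#' inner diameters, the rule of thumb under which Poiseuille's law applies
#' to the whole tube.
#'
#' @param length tube length in mm
#' @param inner_diameter lumen diameter in mm
#' @return an object of class `tube_geometry`
#' @export
tube_geometry <- function(length, inner_diameter) {
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) || length <= 0 ||
      !is.numeric(inner_diameter) || length(inner_diameter) != 1L ||
      !is.finite(inner_diameter) || inner_diameter <= 0) {
    stop_df("length and inner_diameter must be single positive numbers (mm)",
            "invalid_geometry")
  }
  structure(list(length = length,
                 inner_diameter = inner_diameter,
                 fully_developed = length > 5 * inner_diameter),
            class = "tube_geometry")
}

#' Segment specification
#'
#' Describes one mounted duct segment: its ex vivo length, the axial stretch
#' applied on the bench (mounted length = ex vivo length x stretch ratio),
#' and the wall thickness measured from histology.
#'
#' @param segment_id label for the segment
#' @param ex_vivo_length unloaded length in mm
#' @param stretch_ratio axial stretch, e.g. 1.30 for 30% stretch
#' @param wall_thickness wall thickness t in mm
#' @param mounted_length optional override in mm; defaults to
#'   `ex_vivo_length * stretch_ratio` and must agree with it within 1%
#' @return an object of class `segment_spec`
#' @export
segment_spec <- function(segment_id, ex_vivo_length, stretch_ratio = 1.30,
                         wall_thickness = 0.11, mounted_length = NULL) {
  if (ex_vivo_length <= 0 || stretch_ratio <= 0) {
    stop_df("ex_vivo_length and stretch_ratio must be positive", "invalid_segment")
  }
  if (wall_thickness <= 0) {
    stop_df("wall_thickness must be positive (mm)", "invalid_segment")
  }
  expected <- ex_vivo_length * stretch_ratio
  if (is.null(mounted_length)) {
    mounted_length <- expected
  } else if (abs(mounted_length - expected) > 0.01 * expected) {
    stop_df(sprintf(
      "mounted_length (%.3f) inconsistent with ex_vivo_length * stretch_ratio (%.3f)",
      mounted_length, expected), "invalid_segment")
  }
  structure(list(segment_id = as.character(segment_id),
                 ex_vivo_length = ex_vivo_length,
                 stretch_ratio = stretch_ratio,
                 mounted_length = mounted_length,
                 wall_thickness = wall_thickness),
            class = "segment_spec")
}

#' Bench measurement series for one segment
#'
#' Aligned vectors of applied total pressure gradient (cmH2O), measured
#' steady volumetric flow (mL/min) and outer diameter (mm), one entry per
#' pressure step.
#'
#' @param segment a [segment_spec()]
#' @param dp_total total pressure gradients, cmH2O, non-negative and
#'   strictly increasing
#' @param flow volumetric flow rates, mL/min, non-negative
#' @param d_out outer diameters, mm, each larger than the wall thickness
#' @return an object of class `bench_series`
#' @export
bench_series <- function(segment, dp_total, flow, d_out) {
  stopifnot(inherits(segment, "segment_spec"))
  n <- length(dp_total)
  if (n < 2L || length(flow) != n || length(d_out) != n) {
    stop_df("dp_total, flow and d_out must have equal length >= 2", "invalid_series")
  }
  if (any(!is.finite(dp_total)) || any(dp_total < 0) || any(diff(dp_total) <= 0)) {
    stop_df("dp_total must be non-negative and strictly increasing", "invalid_series")
  }
  if (any(!is.finite(flow)) || any(flow < 0)) {
    stop_df("flow must be non-negative and finite", "invalid_series")
  }
  if (any(!is.finite(d_out)) || any(d_out <= segment$wall_thickness)) {
    stop_df("d_out must exceed the wall thickness at every step", "invalid_series")
  }
  structure(list(segment = segment, dp_total = dp_total,
                 flow = flow, d_out = d_out),
            class = "bench_series")
}

#' @export
print.bench_series <- function(x, ...) {
  cat(sprintf("<bench_series> segment %s: %d pressure steps, dp %g-%g cmH2O\n",
              x$segment$segment_id, length(x$dp_total),
              min(x$dp_total), max(x$dp_total)))
  invisible(x)
}
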