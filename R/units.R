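# Unit conventions.
#
# All user-facing quantities are in bench units: pressure in cmH2O, flow in
# mL/min, length/diameter in mm, viscosity in cP, hydraulic resistance in
# cmH2O.min/mL.  Conversion to SI happens only inside the Poiseuille
# computation.

#' Unit conversion constants
#'
#' Conventional conversion factors between the bench units used throughout
#' the package and SI.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{cmH2O_Pa}{pascal per centimetre of water column (98.0665)}
#'   \item{cP_PaS}{pascal-second per centipoise (1e-3)}
#'   \item{mL_min_m3s}{cubic metre per second per (mL/min) (1e-6/60)}
#' }
#' @export
df_units <- list(
  cmH2O_Pa   = 98.0665,
  cP_PaS     = 1e-3,
  mL_min_m3s = 1e-6 / 60
)

#' Convert a hydraulic resistance between bench units and SI
#'
#' Bench resistance is expressed in cmH2O.min/mL, SI resistance in
#' Pa.s/m^3. The two functions are exact inverses.
#'
#' @param r_bench resistance in cmH2O.min/mL
#' @param r_si resistance in Pa.s/m^3
#' @return the resistance in the other unit system
#' @export
resistance_to_si <- function(r_bench) {
  r_bench * df_units$cmH2O_Pa / df_units$mL_min_m3s
}

#' @rdname resistance_to_si
#' @export
resistance_from_si <- function(r_si) {
  r_si * df_units$mL_min_m3s / df_units$cmH2O_Pa
}
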