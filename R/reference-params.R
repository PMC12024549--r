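#' Published valve-model parameters for the five tested duct segments
#'
#' The fitted sigmoid parameters reported for the five single-valve
#' porcine thoracic-duct segments: the open-valve plateau `r_vl`, the
#' resistance span `r_vh` and the transition steepness `s`. Note the huge
#' specimen-to-specimen spread of `r_vh` (about eight orders of magnitude),
#' which is why the fitting machinery works on log-transformed parameters.
#'
#' @return a data.frame with columns `segment_id`, `r_vl`
#'   (cmH2O.min/mL), `r_vh` (cmH2O.min/mL), `s` (1/cmH2O)
#' @export
td_reference_parameters <- function() {
  data.frame(
    segment_id = paste0("TD", 1:5),
    r_vl = c(0.088, 0.085, 0.154, 0.011, 0.071),
    r_vh = c(1.54e4, 6.42e10, 6.33e7, 7.38e9, 9.09e2),
    s    = c(25.4, 85.8, 28.5, 19, 14.5)
  )
}
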