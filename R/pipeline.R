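# Pipeline orchestration: configuration, per-segment analysis, run
# entry points and provenance.

#' Run configuration
#'
#' Collects every tunable of the pipeline with defaults matching the bench
#' protocol: 0.7 cP saline, a 3 mm x 31 mm rigid phantom, the as-printed
#' inner-diameter convention, absolute-residual fitting with 5 Nelder-Mead
#' starts.
#'
#' @param phantom_path path to the phantom calibration CSV
#' @param bench_path path to the bench measurement CSV
#' @param segments_path path to the segment geometry CSV
#' @param viscosity_cP fluid viscosity, cP
#' @param phantom_length_mm,phantom_diameter_mm phantom geometry, mm
#' @param diameter_convention `"as-printed"` or `"geometric"`, see
#'   [inner_diameter()]
#' @param dp_valve_input `"observed"` or `"mapped"`, see [analyze_segment()]
#' @param objective valve-fit residual mode, see [fit_valve_model()]
#' @param multistart number of valve-fit starts
#' @param seed integer seed for all randomness in the run
#' @param out_dir directory for result files
#' @return an object of class `run_config`
#' @export
run_config <- function(phantom_path = NULL, bench_path = NULL,
                       segments_path = NULL,
                       viscosity_cP = 0.7,
                       phantom_length_mm = 31, phantom_diameter_mm = 3,
                       diameter_convention = c("as-printed", "geometric"),
                       dp_valve_input = c("observed", "mapped"),
                       objective = c("absolute", "log"),
                       multistart = 5L, seed = 1L, out_dir = ".") {
  structure(list(phantom_path = phantom_path, bench_path = bench_path,
                 segments_path = segments_path,
                 viscosity_cP = viscosity_cP,
                 phantom_length_mm = phantom_length_mm,
                 phantom_diameter_mm = phantom_diameter_mm,
                 diameter_convention = match.arg(diameter_convention),
                 dp_valve_input = match.arg(dp_valve_input),
                 objective = match.arg(objective),
                 multistart = as.integer(multistart),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_fluid <- function(config) fluid_properties(config$viscosity_cP)
config_phantom_tube <- function(config) {
  tube_geometry(config$phantom_length_mm, config$phantom_diameter_mm)
}

# polynomial rolling hash (mod the Mersenne prime 2^31 - 1) over the
# canonical JSON of the config: a stable content fingerprint without
# external digest dependencies; all intermediates stay below 2^53
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(s)) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

write_provenance <- function(config, path) {
  prov <- list(config = unclass(config),
               config_hash = config_hash(config),
               seed = config$seed,
               package = "ductflow",
               version = as.character(utils::packageVersion("ductflow")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Calibrate the connector resistance from a phantom table
#'
#' Reads the phantom CSV, fits the pressure-flow line, subtracts the
#' phantom's Poiseuille resistance, writes `calibration.json` and a
#' provenance record into `config$out_dir`.
#'
#' @param config a [run_config()] with `phantom_path` set
#' @return the [connector_resistance()] calibration
#' @export
run_calibrate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  exp <- read_phantom_table(config$phantom_path, config_phantom_tube(config))
  cal <- calibrate_connector(exp, config_fluid(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(cal),
                       file.path(config$out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(config, file.path(config$out_dir, "provenance_calibrate.json"))
  message(sprintf(
    "calibrate: slope %.6g, R_phantom %.6g, R_conn %.6g cmH2O.min/mL (linear R^2 %.4f)",
    cal$slope, cal$r_phantom, cal$r_conn, cal$r_squared_linear))
  cal
}

#' Analyse one bench series end to end
#'
#' Decomposes resistances, fits the exponential valve-pressure map and the
#' valve sigmoid, computes the opening threshold, and validates the fit by
#' forward flow prediction against the measured flows.
#'
#' By default the sigmoid is fitted against the decomposed per-step valve
#' gradients and the flow validation evaluates it at those same gradients,
#' which makes the whole chain exact on noise-free data.
#' `dp_valve_input = "mapped"` instead feeds the sigmoid fit the smoothed
#' gradients from the exponential map; that guarantees positive, monotone
#' gradient values on noisy data, but whenever the true gradient curve is
#' not exponential the smoothing biases the transition-region points that
#' identify `r_vh` and `s` (see the methods vignette). The map-based flow
#' prediction is always computed and reported as `r_squared_flow_map`.
#'
#' @param series a [bench_series()]
#' @param r_conn calibrated connector resistance, cmH2O.min/mL
#' @param fluid a [fluid_properties()]
#' @param convention inner-diameter convention
#' @param dp_valve_input `"observed"` (default) or `"mapped"`: which valve
#'   gradients the sigmoid fit consumes
#' @param objective,multistart,seed valve-fit options, see [fit_valve_model()]
#' @return a list of class `valve_fit`: `segment_id`, `model`,
#'   `pressure_map`, `threshold`, `r_squared_resistance`, `r_squared_flow`,
#'   `r_squared_flow_map`, `resistance_series`, `predicted_flow`
#' @export
analyze_segment <- function(series, r_conn, fluid = fluid_properties(),
                            convention = "as-printed",
                            dp_valve_input = c("observed", "mapped"),
                            objective = "absolute", multistart = 5L,
                            seed = 1L) {
  dp_valve_input <- match.arg(dp_valve_input)
  rs <- decompose_resistance(series, r_conn, fluid, convention)
  if (nrow(rs) < 3L) {
    stop_df(sprintf("segment %s: fewer than 3 non-zero-flow steps",
                    attr(rs, "segment_id")), "insufficient_data")
  }
  pmap <- fit_pressure_map(rs$dp_total, rs$dp_valve)
  dpv_fit <- if (dp_valve_input == "mapped") {
    eval_pressure_map(pmap, rs$dp_total)
  } else {
    rs$dp_valve
  }
  vfit <- fit_valve_model(dpv_fit, rs$r_valve,
                          objective = objective, multistart = multistart,
                          seed = seed)
  q_pred <- predict_flow(rs$dp_total, vfit$model, r_conn = r_conn,
                         r_vessel = rs$r_vessel, dp_valve = rs$dp_valve)
  q_pred_map <- predict_flow(rs$dp_total, vfit$model, pmap,
                             r_conn = r_conn, r_vessel = rs$r_vessel)
  structure(list(segment_id = attr(rs, "segment_id"),
                 model = vfit$model,
                 pressure_map = pmap,
                 threshold = valve_opening_threshold(vfit$model),
                 r_squared_resistance = vfit$r_squared_resistance,
                 r_squared_flow = coefficient_of_determination(q_pred, rs$flow),
                 r_squared_flow_map = coefficient_of_determination(q_pred_map, rs$flow),
                 resistance_series = rs,
                 predicted_flow = q_pred),
            class = "valve_fit")
}

#' Analyse all segments in the configured bench tables
#'
#' Runs [analyze_segment()] per segment, writing the fit-results table, the
#' per-step resistance table, a JSON summary (threshold mean +/- sd and the
#' spread of both R^2 values) and a provenance record to `config$out_dir`.
#' Segments with fewer than 3 non-zero-flow steps are skipped with a
#' warning and listed in the summary.
#'
#' @param config a [run_config()] with `bench_path` and `segments_path` set
#' @param calibration a `connector_calibration`, or a number taken as
#'   `r_conn` directly
#' @return a list with `fits` (named list of `valve_fit`), `summary`, and
#'   `skipped`
#' @export
run_analyze <- function(config, calibration) {
  stopifnot(inherits(config, "run_config"))
  r_conn <- if (inherits(calibration, "connector_calibration")) {
    calibration$r_conn
  } else {
    as.numeric(calibration)
  }
  all_series <- read_bench_tables(config$bench_path, config$segments_path)
  fluid <- config_fluid(config)
  fits <- list()
  skipped <- character(0)
  for (id in names(all_series)) {
    fit <- tryCatch(
      analyze_segment(all_series[[id]], r_conn, fluid,
                      convention = config$diameter_convention,
                      dp_valve_input = config$dp_valve_input,
                      objective = config$objective,
                      multistart = config$multistart, seed = config$seed),
      ductflow_error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("segment %s skipped: %s", id, conditionMessage(fit)))
      skipped <- c(skipped, id)
    } else {
      message(sprintf(
        "analyze %s: Rvl %.4g, Rvh %.4g, s %.4g, threshold %.3f cmH2O, R2(res) %.4f, R2(flow) %.4f",
        id, fit$model$r_vl, fit$model$r_vh, fit$model$s, fit$threshold,
        fit$r_squared_resistance, fit$r_squared_flow))
      fits[[id]] <- fit
    }
  }
  if (length(fits) == 0L) {
    stop_df("no segment could be analysed", "empty_series")
  }
  thr <- threshold_summary(fits)
  r2r <- vapply(fits, `[[`, numeric(1), "r_squared_resistance")
  r2f <- vapply(fits, `[[`, numeric(1), "r_squared_flow")
  summary <- list(n_segments = length(fits),
                  skipped = skipped,
                  threshold_mean = thr$mean, threshold_sd = thr$sd,
                  r2_resistance_mean = mean(r2r), r2_resistance_sd = stats::sd(r2r),
                  r2_flow_mean = mean(r2f), r2_flow_sd = stats::sd(r2f))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fit_results(fits, file.path(config$out_dir, "fit_results.csv"))
  res_tab <- do.call(rbind, lapply(fits, function(f) {
    cbind(segment_id = f$segment_id, as.data.frame(f$resistance_series))
  }))
  utils::write.csv(res_tab, file.path(config$out_dir, "resistance_series.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(config, file.path(config$out_dir, "provenance_analyze.json"))
  list(fits = fits, summary = summary, skipped = skipped)
}

#' Validate existing fits by forward flow prediction only
#'
#' @param fits list of `valve_fit` objects (from [run_analyze()])
#' @return data.frame with `segment_id` and `R2_flow`
#' @export
run_validate <- function(fits) {
  data.frame(segment_id = vapply(fits, `[[`, character(1), "segment_id"),
             R2_flow = vapply(fits, `[[`, numeric(1), "r_squared_flow"))
}

#' Simulate a synthetic bench dataset to the canonical CSVs
#'
#' Writes the bench and segment tables plus a ground-truth JSON sidecar
#' (true parameters, noise settings, seed) for test harnesses.
#'
#' @param truths list of [synthetic_ground_truth()] (segment ids must be
#'   unique)
#' @param out_dir destination directory
#' @param grid a [pressure_grid()]
#' @return invisibly, the output directory
#' @export
run_simulate <- function(truths, out_dir, grid = pressure_grid()) {
  if (inherits(truths, "synthetic_ground_truth")) truths <- list(truths)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  series <- lapply(truths, generate_segment_series, grid = grid)
  write_bench_tables(series,
                     file.path(out_dir, "bench_data.csv"),
                     file.path(out_dir, "segments.csv"))
  sidecar <- lapply(truths, function(tr) {
    list(segment_id = tr$segment$segment_id,
         r_vl = tr$valve$r_vl, r_vh = tr$valve$r_vh, s = tr$valve$s,
         threshold = valve_opening_threshold(tr$valve),
         r_conn = tr$r_conn,
         d_min = tr$d_min, d_max = tr$d_max, p_half = tr$p_half,
         noise_flow = tr$noise_flow, noise_diameter = tr$noise_diameter,
         seed = tr$seed)
  })
  jsonlite::write_json(sidecar, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
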