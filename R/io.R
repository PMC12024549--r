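# Readers and writers for the canonical plain-text bench tables.
#
# Bench-data CSV:  segment_id, dp_total_cmH2O, Q_mL_min, Dout_mm
# Segment CSV:     segment_id, ex_vivo_length_mm, stretch_ratio, wall_thickness_mm
# Phantom CSV:     dp_total_cmH2O, Q_mL_min
# All files: header row, decimal point, UTF-8.

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) {
    stop_df(sprintf("file not found: %s", path), "io_error")
  }
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop_df(sprintf("cannot read %s: %s", path, conditionMessage(e)),
                           "io_error")
                 })
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_df(sprintf("%s: missing required column(s): %s",
                    path, paste(missing, collapse = ", ")), "io_error")
  }
  if (nrow(df) == 0L) {
    stop_df(sprintf("%s: no data rows", path), "io_error")
  }
  df
}

#' Read a phantom calibration table
#'
#' @param path CSV with columns `dp_total_cmH2O`, `Q_mL_min`
#' @param tube the phantom [tube_geometry()]
#' @return a [phantom_experiment()]
#' @export
read_phantom_table <- function(path, tube = tube_geometry(31, 3)) {
  df <- read_checked_csv(path, c("dp_total_cmH2O", "Q_mL_min"))
  df <- df[order(df$dp_total_cmH2O), , drop = FALSE]
  phantom_experiment(df$dp_total_cmH2O, df$Q_mL_min, tube)
}

#' Read bench measurement and segment tables
#'
#' The bench table holds one row per segment per pressure step; the
#' companion segment table holds per-segment geometry.
#'
#' @param bench_path CSV with columns `segment_id`, `dp_total_cmH2O`,
#'   `Q_mL_min`, `Dout_mm`
#' @param segments_path CSV with columns `segment_id`,
#'   `ex_vivo_length_mm`, `stretch_ratio`, `wall_thickness_mm`
#' @return a named list of [bench_series()], one per segment
#' @export
read_bench_tables <- function(bench_path, segments_path) {
  bench <- read_checked_csv(bench_path,
                            c("segment_id", "dp_total_cmH2O", "Q_mL_min", "Dout_mm"))
  segs <- read_checked_csv(segments_path,
                           c("segment_id", "ex_vivo_length_mm",
                             "stretch_ratio", "wall_thickness_mm"))
  extra <- setdiff(unique(bench$segment_id), segs$segment_id)
  if (length(extra) > 0L) {
    stop_df(sprintf("bench table references segment(s) missing from segment table: %s",
                    paste(extra, collapse = ", ")), "io_error")
  }
  out <- lapply(seq_len(nrow(segs)), function(i) {
    row <- segs[i, ]
    sub <- bench[bench$segment_id == row$segment_id, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sub <- sub[order(sub$dp_total_cmH2O), , drop = FALSE]
    spec <- segment_spec(row$segment_id, row$ex_vivo_length_mm,
                         row$stretch_ratio, row$wall_thickness_mm)
    bench_series(spec, sub$dp_total_cmH2O, sub$Q_mL_min, sub$Dout_mm)
  })
  names(out) <- segs$segment_id
  out[!vapply(out, is.null, logical(1))]
}

#' Write a bench series (plus segment row) to the canonical CSVs
#'
#' @param series a [bench_series()] or list thereof
#' @param bench_path,segments_path destination CSV paths
#' @return invisibly, the two paths
#' @export
write_bench_tables <- function(series, bench_path, segments_path) {
  if (inherits(series, "bench_series")) series <- list(series)
  bench <- do.call(rbind, lapply(series, function(s) {
    data.frame(segment_id = s$segment$segment_id,
               dp_total_cmH2O = s$dp_total, Q_mL_min = s$flow,
               Dout_mm = s$d_out)
  }))
  segs <- do.call(rbind, lapply(series, function(s) {
    data.frame(segment_id = s$segment$segment_id,
               ex_vivo_length_mm = s$segment$ex_vivo_length,
               stretch_ratio = s$segment$stretch_ratio,
               wall_thickness_mm = s$segment$wall_thickness)
  }))
  utils::write.csv(bench, bench_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(segs, segments_path, row.names = FALSE, quote = FALSE)
  invisible(c(bench_path, segments_path))
}

# resistances serialized with >= 6 significant digits; Rvh in scientific form
format_sig <- function(x, digits = 8L) {
  formatC(x, digits = digits, format = "g")
}

#' Write the per-segment fit-results table
#'
#' @param fits list of per-segment fit results from [analyze_segment()]
#' @param path destination CSV
#' @return invisibly, `path`
#' @export
write_fit_results <- function(fits, path) {
  df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(segment_id = f$segment_id,
               Rvl = format_sig(f$model$r_vl),
               Rvh = formatC(f$model$r_vh, digits = 6, format = "e"),
               s = format_sig(f$model$s),
               P0 = format_sig(f$pressure_map$p0),
               A = format_sig(f$pressure_map$a),
               threshold_cmH2O = format_sig(f$threshold),
               R2_resistance = format_sig(f$r_squared_resistance),
               R2_flow = format_sig(f$r_squared_flow))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
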