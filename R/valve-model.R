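# Sigmoidal valve-resistance model, exponential valve-pressure map,
# forward flow prediction, and the valve-opening threshold.
#
# The valve's resistance to forward flow is modelled as a logistic function
# of the pressure gradient across the valve:
#
#   R_valve^m(dp) = R_vl + R_vh / (1 + exp(s * dp))
#
# R_vl is the low-resistance plateau reached when the valve is fully open,
# R_vl + R_vh the maximal resistance at large adverse gradients, and s the
# steepness of the open/closed transition. All three are positive; fits are
# performed on log-transformed parameters so an unconstrained Nelder-Mead
# simplex respects the bounds (and because R_vh spans many orders of
# magnitude across specimens).

#' Sigmoidal valve-resistance model
#'
#' @param r_vl low-resistance plateau (valve fully open), cmH2O.min/mL
#' @param r_vh resistance span; the maximum resistance is `r_vl + r_vh`
#' @param s transition steepness, 1/cmH2O
#' @return an object of class `valve_resistance_model`
#' @export
valve_resistance_model <- function(r_vl, r_vh, s) {
  if (!all(is.finite(c(r_vl, r_vh, s))) || r_vl <= 0 || r_vh <= 0 || s <= 0) {
    stop_df("r_vl, r_vh and s must all be positive and finite", "invalid_model")
  }
  structure(list(r_vl = r_vl, r_vh = r_vh, s = s),
            class = "valve_resistance_model")
}

#' Evaluate the valve-resistance sigmoid
#'
#' `r_vl + r_vh / (1 + exp(s * dp_valve))`, computed through the logistic
#' CDF so the exponential never overflows: the value tends to `r_vl` as
#' `dp_valve -> +Inf` and to `r_vl + r_vh` as `dp_valve -> -Inf`.
#'
#' @param model a [valve_resistance_model()]
#' @param dp_valve pressure gradient across the valve, cmH2O (vectorised)
#' @return valve resistance, cmH2O.min/mL
#' @export
eval_valve_resistance <- function(model, dp_valve) {
  stopifnot(inherits(model, "valve_resistance_model"))
  # 1/(1 + exp(x)) == plogis(-x), stable for |x| up to and past +-700
  model$r_vl + model$r_vh * stats::plogis(-model$s * dp_valve)
}

#' Exponential valve-pressure map
#'
#' Empirical map from the applied total pressure gradient to the (positive)
#' pressure gradient across the valve: `dp_valve^m = P0 exp(A dp_total)`.
#' P0 (> 0) is the valve gradient extrapolated to zero applied gradient; A
#' is unbounded.
#'
#' @param p0 cmH2O, positive
#' @param a 1/cmH2O
#' @return an object of class `exponential_pressure_model`
#' @export
exponential_pressure_model <- function(p0, a) {
  if (!all(is.finite(c(p0, a))) || p0 <= 0) {
    stop_df("p0 must be positive and finite", "invalid_model")
  }
  structure(list(p0 = p0, a = a), class = "exponential_pressure_model")
}

#' @rdname exponential_pressure_model
#' @param model an `exponential_pressure_model`
#' @param dp_total applied total pressure gradient, cmH2O (vectorised)
#' @export
eval_pressure_map <- function(model, dp_total) {
  stopifnot(inherits(model, "exponential_pressure_model"))
  model$p0 * exp(model$a * dp_total)
}

# Nelder-Mead with one restart from the optimum; the simplex can collapse
# prematurely, and a restart rebuilds it around the best point.
nm_minimize <- function(par, fn, maxit = 2000L) {
  opt <- stats::optim(par, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-14))
  opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-14))
  if (opt2$value <= opt$value) opt2 else opt
}

#' Fit the exponential valve-pressure map
#'
#' Least-squares fit of `P0 exp(A dp_total)` to observed valve pressure
#' gradients by Nelder-Mead, with P0 kept positive through a log
#' parameterisation. The initial guess comes from the log-linear regression
#' `log(dp_valve) ~ dp_total`, which is already the exact solution for
#' noise-free exponential data. Non-positive `dp_valve` points carry no
#' information for this positive map and are dropped with a warning.
#'
#' @param dp_total applied total pressure gradients, cmH2O
#' @param dp_valve valve pressure gradients from [decompose_resistance()], cmH2O
#' @return an [exponential_pressure_model()]
#' @export
fit_pressure_map <- function(dp_total, dp_valve) {
  stopifnot(length(dp_total) == length(dp_valve))
  keep <- is.finite(dp_valve) & dp_valve > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d non-positive dp_valve point(s) from pressure-map fit",
                    sum(!keep)))
  }
  dp_total <- dp_total[keep]
  dp_valve <- dp_valve[keep]
  if (length(dp_valve) < 2L) {
    stop_df("fewer than 2 positive dp_valve points; cannot fit pressure map",
            "insufficient_data")
  }
  init <- stats::coef(stats::lm(log(dp_valve) ~ dp_total))
  obj <- function(par) {
    pred <- exp(par[1]) * exp(par[2] * dp_total)
    sum((pred - dp_valve)^2)
  }
  opt <- nm_minimize(c(init[[1]], init[[2]]), obj)
  exponential_pressure_model(p0 = exp(opt$par[1]), a = opt$par[2])
}

# deterministic scale-aware starting point for the sigmoid fit
valve_fit_init <- function(dp_valve, r_valve) {
  r_min <- max(min(r_valve), 1e-12)
  span  <- max(max(r_valve) - min(r_valve), 1e-6 * r_min)
  s0    <- 10 / max(diff(range(dp_valve)), 1e-6)
  log(c(r_vl = r_min, r_vh = span, s = s0))
}

#' Fit the sigmoidal valve-resistance model
#'
#' Minimises the summed squared residuals between the sigmoid and the
#' decomposed per-step valve resistances over `(r_vl, r_vh, s)`, optimising
#' the log-transformed parameters with Nelder-Mead. Because the surface has
#' local minima when the data barely sample the high-resistance branch, the
#' deterministic scale-aware start is complemented by `multistart - 1`
#' jittered starts drawn from a fixed seed; the best objective wins.
#'
#' The default objective works on absolute residuals (matching the plain
#' least-squares default of common fitting tools); `objective = "log"`
#' fits log-residuals instead, which weights the low plateau and the high
#' branch evenly when `r_vh` is many orders of magnitude above `r_vl`.
#'
#' @param dp_valve valve pressure gradients (typically the fitted pressure
#'   map evaluated at each applied gradient), cmH2O
#' @param r_valve decomposed valve resistances, cmH2O.min/mL
#' @param objective `"absolute"` (default) or `"log"` residuals
#' @param multistart number of Nelder-Mead starts (>= 1), default 5
#' @param seed integer seed for the deterministic jittered starts
#' @return a list with `model` (a [valve_resistance_model()]),
#'   `r_squared_resistance`, `objective_value` and `convergence`
#' @export
fit_valve_model <- function(dp_valve, r_valve,
                            objective = c("absolute", "log"),
                            multistart = 5L, seed = 1L) {
  objective <- match.arg(objective)
  stopifnot(length(dp_valve) == length(r_valve))
  if (length(r_valve) < 3L) {
    stop_df("need at least 3 points to fit the 3-parameter valve model",
            "insufficient_data")
  }
  if (objective == "log" && any(r_valve <= 0)) {
    stop_df("log objective requires strictly positive r_valve", "invalid_data")
  }
  obj <- function(par) {
    m <- exp(par)
    pred <- m[1] + m[2] * stats::plogis(-m[3] * dp_valve)
    if (objective == "log") sum((log(pred) - log(r_valve))^2)
    else sum((pred - r_valve)^2)
  }
  init <- valve_fit_init(dp_valve, r_valve)
  starts <- list(init)
  if (multistart > 1L) {
    jitters <- with_preserved_rng(seed, {
      lapply(seq_len(multistart - 1L), function(i) {
        init + stats::rnorm(3L, sd = c(0.5, 2.0, 0.7))
      })
    })
    starts <- c(starts, jitters)
  }
  best <- NULL
  for (st in starts) {
    opt <- nm_minimize(st, obj, maxit = 5000L)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value)) {
    stop_df("valve-model fit failed to produce a finite objective",
            "non_convergence")
  }
  par <- unname(exp(best$par))
  model <- valve_resistance_model(par[1], par[2], par[3])
  fitted <- eval_valve_resistance(model, dp_valve)
  list(model = model,
       r_squared_resistance = coefficient_of_determination(fitted, r_valve),
       objective_value = best$value,
       convergence = best$convergence)
}

#' Model-based forward flow prediction
#'
#' Predicts the steady flow at each applied pressure gradient from the
#' fitted models and the series resistances:
#' `Q^m = dp_total / (R_conn + R_vessel + R_valve^m)`, where `R_vessel`
#' uses the diameter measured at the same step. The valve gradient entering
#' the sigmoid is taken from `dp_valve` when supplied (typically the
#' decomposed per-step gradients, making the prediction exact on noise-free
#' data); otherwise it comes from the fitted exponential pressure map
#' evaluated at `dp_total`.
#'
#' @param dp_total applied total pressure gradients, cmH2O
#' @param valve_model a [valve_resistance_model()]
#' @param pressure_map an [exponential_pressure_model()], used when
#'   `dp_valve` is `NULL`
#' @param r_conn connector resistance, cmH2O.min/mL
#' @param r_vessel per-step vessel resistances aligned with `dp_total`
#' @param dp_valve optional per-step valve pressure gradients, cmH2O
#' @return predicted flow, mL/min
#' @export
predict_flow <- function(dp_total, valve_model, pressure_map = NULL,
                         r_conn, r_vessel, dp_valve = NULL) {
  stopifnot(length(r_vessel) == length(dp_total))
  if (is.null(dp_valve)) {
    if (is.null(pressure_map)) {
      stop_df("supply either dp_valve or a fitted pressure_map", "invalid_model")
    }
    dp_valve <- eval_pressure_map(pressure_map, dp_total)
  }
  stopifnot(length(dp_valve) == length(dp_total))
  r_valve_m <- eval_valve_resistance(valve_model, dp_valve)
  denom <- r_conn + r_vessel + r_valve_m
  if (any(denom <= 0)) {
    stop_df("non-positive total model resistance", "invalid_model")
  }
  dp_total / denom
}

#' Valve-opening pressure threshold
#'
#' The gradient at which the modelled valve resistance has fallen to within
#' 5% of its open plateau `r_vl`: the closed form
#' `(1/s) ln(r_vh / (0.05 r_vl))`. (The exact inversion of the sigmoid
#' carries an additional `- 1` inside the logarithm that is negligible
#' whenever `r_vh >> 0.05 r_vl`; the closed form as printed omits it.)
#'
#' @param model a [valve_resistance_model()]
#' @return threshold pressure gradient, cmH2O
#' @export
valve_opening_threshold <- function(model) {
  stopifnot(inherits(model, "valve_resistance_model"))
  log(model$r_vh / (0.05 * model$r_vl)) / model$s
}

#' Summarise opening thresholds across segments
#'
#' @param fits a list of per-segment fit results (each carrying a
#'   `threshold` field or a `model` to evaluate), or a numeric vector of
#'   thresholds
#' @return a list with `per_segment`, `mean` and `sd` (population
#'   convention, normalising by n)
#' @export
threshold_summary <- function(fits) {
  if (is.numeric(fits)) {
    thr <- fits
  } else if (is.list(fits) && length(fits) > 0L) {
    thr <- vapply(fits, function(f) {
      if (!is.null(f$threshold)) f$threshold
      else valve_opening_threshold(f$model)
    }, numeric(1))
  } else {
    stop_df("need at least one fit to summarise", "empty_input")
  }
  if (length(thr) == 0L) stop_df("need at least one fit to summarise", "empty_input")
  m <- mean(thr)
  list(per_segment = thr, mean = m, sd = sqrt(mean((thr - m)^2)))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken about
#' the mean of the data. Mathematically this can be negative for a model
#' worse than the mean; it is reported as computed.
#'
#' @param model_values model-estimated values
#' @param data_values observed values (not all identical)
#' @return R^2, dimensionless
#' @export
coefficient_of_determination <- function(model_values, data_values) {
  stopifnot(length(model_values) == length(data_values))
  if (length(data_values) < 2L) {
    stop_df("need at least 2 points for R^2", "insufficient_data")
  }
  ss_tot <- sum((data_values - mean(data_values))^2)
  if (ss_tot == 0) {
    stop_df("all data values identical; R^2 undefined", "undefined_r_squared")
  }
  1 - sum((model_values - data_values)^2) / ss_tot
}
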