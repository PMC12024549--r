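# Shared fixtures: the five published valve parameter sets and synthetic
# ground truths built from them.

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

table1_models <- function() {
  tab <- td_reference_parameters()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    valve_resistance_model(tab$r_vl[i], tab$r_vh[i], tab$s[i])
  })
  names(out) <- tab$segment_id
  out
}

default_fluid <- function() fluid_properties(0.7)
phantom_tube <- function() tube_geometry(31, 3)

make_truth <- function(valve, seed = 1L, noise_flow = 0, noise_diameter = 0,
                       id = "SYN") {
  synthetic_ground_truth(valve, segment = segment_spec(id, 31),
                         noise_flow = noise_flow,
                         noise_diameter = noise_diameter, seed = seed)
}

# deterministic batch of random ground truths over the documented parameter
# ranges (r_vl in [0.01, 0.2], log10 r_vh in [2, 10], s in [10, 90])
random_truths <- function(n, seed, noise_flow = 0.02, noise_diameter = 0.01) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    valve <- valve_resistance_model(r_vl = runif(1, 0.01, 0.2),
                                    r_vh = 10^runif(1, 2, 10),
                                    s    = runif(1, 10, 90))
    make_truth(valve, seed = seed + i, noise_flow = noise_flow,
               noise_diameter = noise_diameter, id = sprintf("S%02d", i))
  })
}

# exact inversion of the sigmoid at 1.05 * r_vl, solved by bisection:
# the independent oracle for the closed-form threshold
threshold_by_bisection <- function(model, lo = 1e-6, hi = 100, tol = 1e-10) {
  target <- 1.05 * model$r_vl
  f <- function(dp) eval_valve_resistance(model, dp) - target
  stopifnot(f(lo) > 0, f(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
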