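# Shared fixtures: every test builds its data in code; no files on disk.

default_meta <- function(first_leg = "L") {
  measurement_meta(calibration_distance_L1 = 7.3,
                   first_leg_on_start = first_leg)
}

# the simulated race runs past 100 m; cropping at 95 m keeps the full
# 10 x 10 m split table inside the analyzed window
test_start_end <- function(...) {
  start_end_config(end_distance = 95, ...)
}

run_pipeline <- function(cfg, ...) {
  sim <- synthesize_trace(cfg)
  res <- analyze_sprint(sim$trace, default_meta(),
                        start_end = test_start_end(), seed = cfg$seed, ...)
  list(sim = sim, res = res)
}

# detected event times in the simulator's absolute clock
detected_times <- function(res, kind) {
  res$events$time[res$events$kind == kind] + attr(res$trace, "t_start")
}

# Bijective matching of truth events to detected events inside a strict
# interior window.  Returns completeness (every truth event has its own
# detected match within half a period), spuriousness (a detected event
# in the interior that is far from every truth event), and the matched
# time errors.
match_events <- function(det, truth_all, t_lo, t_hi, period) {
  truth <- truth_all[truth_all >= t_lo & truth_all <= t_hi]
  idx <- vapply(truth, function(z) {
    d <- abs(det - z)
    i <- which.min(d)
    if (d[i] < 0.5 * period) i else NA_integer_
  }, integer(1))
  complete <- !anyNA(idx) && !any(duplicated(idx[!is.na(idx)]))
  inside <- det[det > min(truth) & det < max(truth)]
  spurious <- any(vapply(inside, function(z) {
    min(abs(truth_all - z)) >= 0.5 * period
  }, logical(1)))
  errors <- if (complete) det[idx] - truth else rep(NA_real_, length(truth))
  list(complete = complete, spurious = spurious, errors = errors,
       matched = if (complete) det[idx] else NULL, truth = truth)
}
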