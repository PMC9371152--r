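test_that("events of a sinusoidal oscillation land at its extrema", {
  t <- seq(0, 2, by = 0.01)
  v <- 8 + 0.4 * sin(2 * pi * 4.5 * t)
  ev <- detect_step_events(t, v, gait_config())
  td <- ev$time[ev$kind == "touchdown"]
  to <- ev$time[ev$kind == "toeoff"]
  td_true <- 3 / (4 * 4.5) + (0:7) / 4.5           # sin = -1
  to_true <- 1 / (4 * 4.5) + (0:8) / 4.5           # sin = +1
  for (z in td_true[td_true > min(td) - 1e-9 & td_true < max(td) + 1e-9]) {
    expect_lt(min(abs(td - z)), 0.0101)
  }
  for (z in to_true[to_true > min(to) - 1e-9 & to_true < max(to) + 1e-9]) {
    expect_lt(min(abs(to - z)), 0.0101)
  }
  expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))  # strict alternation
  expect_true(all(diff(ev$time) > 0))
})

test_that("a monotone speed curve yields no steps", {
  t <- seq(0, 2, by = 0.01)
  expect_error(detect_step_events(t, 2 + 3 * t, gait_config()),
               class = "ldm_no_steps_error")
})

test_that("step metrics follow the phase-time definitions", {
  ev <- data.frame(index = 1:5,
                   time = c(1.00, 1.10, 1.22, 1.32, 1.44),
                   kind = c("touchdown", "toeoff", "touchdown", "toeoff",
                            "touchdown"),
                   stringsAsFactors = FALSE)
  t <- seq(0.9, 1.6, by = 0.01)
  x <- 9 * (t - 1)                                   # constant 9 m/s
  st <- compute_step_metrics(ev, t, x, rep(9, length(t)))
  expect_equal(st$support_s, c(0.10, 0.10), tolerance = 1e-12)
  expect_equal(st$flight_s, c(0.12, 0.12), tolerance = 1e-12)
  expect_equal(st$step_s, c(0.22, 0.22), tolerance = 1e-12)
  expect_equal(st$frequency_hz, c(1, 1) / 0.22)
  expect_equal(st$length_m, c(1.98, 1.98), tolerance = 1e-9)
  expect_equal(st$mean_speed, c(9, 9), tolerance = 1e-9)
  # identity holds exactly by construction
  expect_identical(st$support_s + st$flight_s, st$step_s)

  # toe-off delimited convention swaps the phase order
  st2 <- compute_step_metrics(ev, t, x, rep(9, length(t)),
                              convention = "toeoff")
  expect_equal(st2$flight_s, 0.12, tolerance = 1e-12)
  expect_equal(st2$support_s, 0.10, tolerance = 1e-12)
  expect_equal(st2$step_s, 0.22, tolerance = 1e-12)
})

test_that("a touchdown pair without a toe-off is skipped and logged", {
  ev <- data.frame(index = 1:6,
                   time = c(1.00, 1.10, 1.22, 1.44, 1.54, 1.66),
                   kind = c("touchdown", "toeoff", "touchdown",
                            "touchdown", "toeoff", "touchdown"),
                   stringsAsFactors = FALSE)
  t <- seq(0.9, 1.8, by = 0.01)
  x <- 9 * (t - 1)
  expect_warning(st <- compute_step_metrics(ev, t, x, rep(9, length(t))),
                 class = "ldm_step_structure_warning")
  expect_equal(attr(st, "skipped"), 2L)
  expect_equal(st$ordinal, c(1L, 3L))                # ordinal continues
  sided <- assign_sides(st, "L")
  expect_equal(sided$side, c("L", "L"))              # parity across the gap
})

test_that("sides alternate from the starting leg", {
  st <- data.frame(ordinal = 1:4, side = "unknown", boundary = FALSE)
  expect_equal(assign_sides(st, "L")$side, c("L", "R", "L", "R"))
  expect_equal(assign_sides(st, "R")$side, c("R", "L", "R", "L"))
  expect_equal(assign_sides(st, "unknown")$side, rep("unknown", 4))
})

test_that("symmetry index: definition, degenerate cases, signed variant", {
  st <- data.frame(ordinal = 1:6, side = rep(c("L", "R"), 3),
                   length_m = c(2.2, 2.0, 2.2, 2.0, 2.2, 2.0),
                   step_s = 0.22, boundary = FALSE)
  si <- symmetry_index(st, "step_length")
  expect_equal(si$symmetry_index, 100 * 0.2 / 2.1, tolerance = 1e-9)
  expect_equal(symmetry_index(st, "step_time")$symmetry_index, 0)
  expect_equal(symmetry_index(st, "step_length", signed = TRUE)$symmetry_index,
               100 * 0.2 / 2.1)
  st$length_m <- rev(st$length_m)
  expect_equal(symmetry_index(st, "step_length", signed = TRUE)$symmetry_index,
               -100 * 0.2 / 2.1)
  st$side <- "L"
  expect_error(symmetry_index(st, "step_length"),
               class = "ldm_symmetry_unavailable_error")
})

test_that("step identities hold for a full simulated analysis", {
  out <- run_pipeline(sim_config(seed = 12, noise_sd = 0))
  st <- out$res$steps
  expect_identical(st$support_s + st$flight_s, st$step_s)
  expect_equal(st$frequency_hz * st$step_s, rep(1, nrow(st)))
  # telescoping of step lengths over consecutive steps
  run <- out$res$trace
  x_at <- function(tm) stats::approx(run$t, run$x, xout = tm)$y
  expect_equal(sum(st$length_m),
               x_at(st$t_next_touchdown[nrow(st)]) - x_at(st$t_touchdown[1]),
               tolerance = 1e-9)
})

test_that("noise-free event recovery is within one sample", {
  out <- run_pipeline(sim_config(seed = 13, noise_sd = 0))
  truth <- out$sim$truth
  t_end <- max(out$res$trace$t) + attr(out$res$trace, "t_start")
  m <- match_events(detected_times(out$res, "touchdown"),
                    truth$touchdown_times, truth$start_time, t_end - 0.5,
                    1 / out$sim$truth$config$step_freq)
  expect_true(m$complete)
  expect_false(m$spurious)
  expect_lt(max(abs(m$errors)), 0.01)
})
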