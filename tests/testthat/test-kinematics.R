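test_that("central-difference velocity is exact up to quadratics", {
  t <- seq(0, 1, by = 0.01)
  expect_equal(compute_velocity(t, t), rep(1, length(t)))

  x <- 1.5 * t^2
  v <- compute_velocity(t, x)
  inner <- 2:(length(t) - 1)
  expect_equal(v[inner], 3 * t[inner], tolerance = 1e-10)

  expect_error(compute_velocity(t[1:2], x[1:2]), class = "ldm_compute_error")
})

test_that("sinusoid differentiation meets the second-order Taylor bound", {
  t <- seq(0, 10, by = 0.01)
  v <- compute_velocity(t, sin(t))
  inner <- 2:(length(t) - 1)
  expect_lt(max(abs(v[inner] - cos(t[inner]))), 2e-5)
})

test_that("acceleration follows the symmetric difference of speed", {
  t <- seq(0, 1, by = 0.01)
  expect_equal(compute_acceleration(t, rep(7, length(t))), rep(0, length(t)))
  expect_equal(compute_acceleration(t, 3 * t), rep(3, length(t)),
               tolerance = 1e-10)
  # worked numbers: speed 8.0 -> 8.4 m/s over 0.02 s gives 20 m/s^2
  a <- compute_acceleration(c(1.00, 1.01, 1.02), c(8.0, 8.2, 8.4))
  expect_equal(a[2], 0.4 / 0.02)

  # velocity then acceleration of a quadratic displacement is exact at
  # points with two interior neighbours
  x <- 2 - 3 * t + 5 * t^2
  aa <- compute_acceleration(t, compute_velocity(t, x))
  expect_equal(aa[3:(length(t) - 2)], rep(10, length(t) - 4),
               tolerance = 1e-9)
})

test_that("speed zones follow the percent-of-peak threshold", {
  expect_error(segment_zones(numeric(0)), class = "ldm_compute_error")

  z <- segment_zones(rep(9, 50), 0.02)
  expect_equal(z$maintenance, c(1L, 50L))
  expect_null(z$ascending)
  expect_null(z$descending)

  # strictly increasing to the last sample: no descending zone, and the
  # maintenance zone starts at the first sample at or above 98% of peak
  v <- seq(0, 10, length.out = 201)
  z <- segment_zones(v, 0.02)
  expect_null(z$descending)
  expect_equal(z$maintenance[1], which(v >= 0.98 * 10)[1])
  expect_equal(z$i_vmax, 201L)

  # symmetric triangle peaking at 10: the band is symmetric around the top
  v <- c(seq(0, 10, length.out = 101), seq(10, 0, length.out = 101)[-1])
  z <- segment_zones(v, 0.02)
  expect_equal(z$maintenance, c(which(v >= 9.8)[1], max(which(v >= 9.8))))
  expect_equal(diff(c(z$maintenance[1], 101L)),
               diff(c(101L, z$maintenance[2])))

  # ties on v_max: first occurrence wins
  expect_equal(segment_zones(c(1, 5, 5, 1))$i_vmax, 2L)
})

test_that("zones partition the index range", {
  set.seed(31)
  for (rep in 1:20) {
    v <- moving_average(cumsum(rnorm(300)), 25)
    z <- segment_zones(v, runif(1, 0.01, 0.2))
    idx <- c(if (!is.null(z$ascending)) z$ascending[1]:z$ascending[2],
             z$maintenance[1]:z$maintenance[2],
             if (!is.null(z$descending)) z$descending[1]:z$descending[2])
    expect_identical(idx, seq_along(v))
  }
})

test_that("section splits: uniform and uniformly accelerated motion", {
  # constant 5 m/s over 100 m: ten splits of 2.000 s
  t <- seq(0, 21, by = 0.01)
  x <- 5 * t
  sp <- section_splits(t, x, rep(5, length(t)))
  expect_equal(nrow(sp[!sp$partial, ]), 10L)
  expect_equal(sp$split_s[1:10], rep(2, 10), tolerance = 1e-9)
  expect_equal(sp$mean_speed[1:10], rep(5, 10), tolerance = 1e-9)
  expect_equal(sp$cumulative_s[10], 20, tolerance = 1e-9)

  # x = 2.5 t^2 (constant a = 5): boundary times sqrt(2 * 10k / 5)
  t <- seq(0, 7, by = 0.01)
  x <- 2.5 * t^2
  sp <- section_splits(t, x, compute_velocity(t, x))
  tk <- sqrt(2 * 10 * (1:10) / 5)
  expect_equal(sp$split_s[1:3], diff(c(0, tk[1:3])), tolerance = 1e-3)
  expect_equal(sp$split_s[1], 2.000, tolerance = 1e-3)

  # telescoping: the ten splits sum exactly to the cumulative 100 m time
  expect_equal(sum(sp$split_s[1:10]), sp$cumulative_s[10], tolerance = 1e-9)

  # trace ending mid-section flags the last row partial
  short <- t <= sqrt(2 * 95 / 5)
  sp2 <- section_splits(t[short], x[short], compute_velocity(t, x)[short])
  expect_true(sp2$partial[nrow(sp2)])
  expect_equal(sum(!sp2$partial), 9L)

  expect_error(section_splits(t[1:50], x[1:50], x[1:50]),
               class = "ldm_compute_error")
})

test_that("an explicit start-line time overrides the interpolated one", {
  t <- seq(0, 21, by = 0.01)
  x <- 5 * t
  sp <- section_splits(t, x, rep(5, length(t)), t0 = -0.1)
  expect_equal(sp$cumulative_s[10], 20.1, tolerance = 1e-9)
})

test_that("kinematic series wires the two velocity streams", {
  sim <- synthesize_trace(sim_config(seed = 4, noise_sd = 0))
  cal <- apply_calibration(sim$trace, 7.3)
  run <- crop_trace(cal, detect_start(cal, test_start_end()),
                    detect_end(cal, test_start_end()), test_start_end())
  kin <- kinematic_series(run)
  expect_equal(length(kin$v_raw), length(kin$t))
  expect_equal(length(kin$a_smooth), length(kin$t))
  # the smoothed stream suppresses the step oscillation the raw one keeps
  osc <- function(v) stats::sd(diff(v))
  expect_lt(osc(kin$v_smooth), 0.2 * osc(kin$v_raw))
  zt <- zone_table(segment_zones(kin$v_smooth), kin$t, kin$x, kin$v_smooth)
  # zones are disjoint index ranges, so summed durations fall short of
  # the total by exactly one sample interval per internal boundary
  expect_equal(sum(zt$duration_s),
               kin$t[length(kin$t)] - kin$t[1] - 2 / kin$nominal_rate,
               tolerance = 1e-9)
})
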