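test_that("moving average: identities and the worked example", {
  expect_equal(moving_average(c(5, 5, 5, 5), 3), c(5, 5, 5, 5))
  y <- rnorm(20)
  expect_equal(moving_average(y, 1), y)
  expect_equal(moving_average(c(0, 1, 2, 3, 4), 3), c(0.5, 1, 2, 3, 3.5))
  expect_error(moving_average(1:5, 0), class = "ldm_config_error")
})

test_that("moving average equals the brute-force windowed mean", {
  brute <- function(y, n, m) {
    lo <- (n - 1L) %/% 2L
    hi <- n %/% 2L
    for (p in seq_len(m)) {
      y <- vapply(seq_along(y), function(i) {
        mean(y[max(1L, i - lo):min(length(y), i + hi)])
      }, numeric(1))
    }
    y
  }
  set.seed(21)
  for (rep in 1:40) {
    y <- rnorm(sample(3:60, 1))
    n <- sample(1:12, 1)
    m <- sample(1:3, 1)
    s <- moving_average(y, n, m)
    expect_equal(s, brute(y, n, m), tolerance = 1e-12)
    expect_true(all(s >= min(y) - 1e-12 & s <= max(y) + 1e-12))
  }
})

make_cal <- function(x, rate = 100) {
  apply_calibration(
    ldm_trace(seq(0, by = 1 / rate, length.out = length(x)), x + 7.3,
              nominal_rate = rate), 7.3)
}

test_that("artifact detection flags spikes and dropouts", {
  # clean 10 m/s motion
  x <- seq(0, 20, by = 0.1)
  expect_equal(nrow(detect_artifacts(make_cal(x))), 0L)

  # one sample displaced by +2 m implies ~200 m/s in and out
  xs <- x
  xs[100] <- xs[100] + 2
  mask <- detect_artifacts(make_cal(xs))
  expect_equal(nrow(mask), 1L)
  expect_equal(mask$start, 100L)
  expect_equal(mask$end, 100L)
  expect_equal(mask$cause, "spike")

  # five missing samples form one dropout segment
  xd <- x
  xd[50:54] <- NaN
  mask <- detect_artifacts(make_cal(xd))
  expect_equal(nrow(mask), 1L)
  expect_equal(mask$start, 50L)
  expect_equal(mask$end, 54L)
  expect_equal(mask$cause, "dropout")

  # a dropout touching the first sample is an edge segment
  xe <- x
  xe[1:3] <- NaN
  expect_equal(detect_artifacts(make_cal(xe))$cause, "edge")
})

test_that("artifact repair interpolates interior segments and crops edges", {
  x <- seq(0, 20, by = 0.1)

  xs <- x
  xs[100] <- xs[100] + 2
  cal <- make_cal(xs)
  rep1 <- repair_artifacts(cal, detect_artifacts(cal))
  expect_equal(rep1$x[100], (xs[99] + xs[101]) / 2)   # midpoint of neighbours
  expect_identical(rep1$x[-100], cal$x[-100])          # others bit-identical

  cal <- make_cal(x)
  expect_identical(repair_artifacts(cal, detect_artifacts(cal)), cal)

  xd <- x
  xd[50:54] <- NaN
  cal <- make_cal(xd)
  rep2 <- repair_artifacts(cal, detect_artifacts(cal))
  expect_equal(rep2$x[50:54], x[50:54], tolerance = 1e-12)  # on the line

  xe <- x
  xe[1:3] <- NaN
  cal <- make_cal(xe)
  rep3 <- repair_artifacts(cal, detect_artifacts(cal))
  expect_length(rep3$x, length(x) - 3L)                # cropped, not guessed

  bad <- make_cal(rep(NaN, 20))
  expect_error(repair_artifacts(bad, detect_artifacts(bad)),
               class = "ldm_repair_error")
})

test_that("start detection follows the 2-SD threshold rule", {
  # flat pre-start, then +0.05 m per sample: sd_pre = 0 so the threshold
  # floor (1 cm) applies; sample 101 is the first above it and holding
  x <- c(rep(0, 100), cumsum(rep(0.05, 120)))
  cal <- make_cal(x)
  i <- detect_start(cal, start_end_config())
  expect_equal(as.integer(i), 101L)
  expect_equal(attr(i, "threshold"), 0.01)

  # translation equivariance: threshold is relative to the pre-start mean
  cal2 <- make_cal(x + 3.33)
  expect_equal(as.integer(detect_start(cal2, start_end_config())), 101L)

  set.seed(5)
  noise <- make_cal(rnorm(300, 0, 0.005))
  expect_error(detect_start(noise, start_end_config()),
               class = "ldm_no_start_error")

  expect_error(detect_start(make_cal(x[1:50]),
                            start_end_config(pre_window = 10)),
               class = "ldm_config_error")
})

test_that("end rule: fixed sample count after the distance crossing", {
  # x rises 0.1 m per sample from 0; with end_distance 6.05 the first
  # sample above it is the 62nd (x = 6.1, 1-based), plus 5 extra -> 67
  # (6.05 rather than 6.0 keeps the crossing clear of float round-off in
  # the 0.1 m grid)
  x <- seq(0, 30, by = 0.1)
  cal <- make_cal(x)
  cfg <- start_end_config(end_distance = 6.05, end_extra_points = 5)
  expect_equal(detect_end(cal, cfg), 62L + 5L)
  cfg0 <- start_end_config(end_distance = 6.05, end_extra_points = 0)
  expect_equal(detect_end(cal, cfg0), 62L)
  expect_error(detect_end(cal, start_end_config(end_distance = 200)),
               class = "ldm_end_not_reached_error")
})

test_that("cropping keeps the configured context and re-zeroes time", {
  x <- seq(0, 150, by = 0.1)
  cal <- make_cal(x)
  cfg <- start_end_config(crop_pad = 1)
  out <- crop_trace(cal, 201L, 1301L, cfg)
  expect_equal(length(out$x), 1401L - 101L + 1L)       # samples [101, 1401]
  expect_equal(attr(out, "start_index"), 101L)
  expect_equal(out$t[attr(out, "start_index")], 0)     # re-zeroed

  out0 <- crop_trace(cal, 201L, 1301L, start_end_config(crop_pad = 0))
  expect_equal(length(out0$x), 1101L)

  clipped <- crop_trace(cal, 50L, 300L, cfg)           # pad hits the edge
  expect_equal(length(clipped$x), 400L)

  expect_error(crop_trace(cal, 300L, 200L, cfg), class = "ldm_config_error")
})

test_that("onset location is exact on noise-free simulated starts", {
  for (amp in c(0.2, 0.6)) {
    sim <- synthesize_trace(sim_config(seed = 2, noise_sd = 0,
                                       osc_amplitude = amp))
    cal <- apply_calibration(sim$trace, 7.3)
    run <- crop_trace(cal, detect_start(cal, test_start_end()),
                      detect_end(cal, test_start_end()), test_start_end())
    t0 <- locate_onset(run, attr(run, "start_index"))
    expect_lt(abs(t0 + attr(run, "t_start") - sim$truth$start_time), 0.01)
  }
})
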