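test_that("the simulator is deterministic for a fixed seed", {
  a <- synthesize_trace(sim_config(seed = 7, dropout_rate = 0.001,
                                   spike_rate = 0.001))
  b <- synthesize_trace(sim_config(seed = 7, dropout_rate = 0.001,
                                   spike_rate = 0.001))
  expect_identical(a$trace$d, b$trace$d)
  expect_identical(a$truth$steps, b$truth$steps)
})

test_that("base velocity: rest, asymptote and the closed form", {
  cfg <- sim_config()
  expect_equal(base_velocity(0, cfg), 0)
  nodecay <- sim_config(decay_rate = 0)
  expect_equal(base_velocity(60, nodecay), nodecay$v_max, tolerance = 1e-9)
  expect_equal(base_velocity(1.3, cfg), 11.5 * (1 - exp(-1)),
               tolerance = 1e-4)
})

test_that("without oscillation the trace integrates the base profile", {
  cfg <- sim_config(noise_sd = 0, osc_amplitude = 0, seed = 2)
  sim <- synthesize_trace(cfg)
  tau <- sim$trace$t - cfg$pre_start_s
  x <- sim$trace$d - cfg$L1
  run <- tau >= 0
  # quadrature oracle, split at the deceleration onset where the profile
  # has a slope break that defeats adaptive quadrature in one piece
  t_on <- stats::uniroot(function(z) {
    cfg$v_max * (z - cfg$tau * (1 - exp(-z / cfg$tau))) - cfg$decay_onset
  }, c(1, 60))$root
  oracle <- vapply(tau[run], function(z) {
    if (z <= t_on) {
      stats::integrate(base_velocity, 0, z, cfg = cfg,
                       rel.tol = 1e-11)$value
    } else {
      stats::integrate(base_velocity, 0, t_on, cfg = cfg,
                       rel.tol = 1e-11)$value +
        stats::integrate(base_velocity, t_on, z, cfg = cfg,
                         rel.tol = 1e-11)$value
    }
  }, numeric(1))
  expect_lt(max(abs(x[run] - oracle)), 1e-6)
})

test_that("ground truth honours the configured cycle structure", {
  cfg <- sim_config(seed = 3, step_freq = 4.5, duty_factor = 0.45)
  truth <- synthesize_trace(cfg)$truth
  st <- ground_truth_summary(truth)
  expect_equal(st$support_s / st$step_s, rep(0.45, nrow(st)),
               tolerance = 1e-9)
  expect_equal(st$support_s + st$flight_s, st$step_s, tolerance = 1e-12)
  expect_equal(st$frequency_hz * st$step_s, rep(1, nrow(st)))
  interior <- !st$boundary
  expect_equal(mean(st$frequency_hz[interior]), cfg$step_freq,
               tolerance = 1e-6)
  # event lists alternate strictly
  ev <- sort(c(truth$touchdown_times, truth$toeoff_times))
  expect_true(all(diff(ev) > 0))
})

test_that("cycle-mean speed matches the base profile", {
  cfg <- sim_config(seed = 1, noise_sd = 0)
  truth <- synthesize_trace(cfg)$truth
  st <- ground_truth_summary(truth)
  interior <- !st$boundary
  base_mean <- mapply(function(a, b) {
    stats::integrate(base_velocity, a - cfg$pre_start_s,
                     b - cfg$pre_start_s, cfg = cfg,
                     rel.tol = 1e-10)$value / (b - a)
  }, st$t_touchdown[interior], st$t_next_touchdown[interior])
  expect_lt(max(abs(st$mean_speed[interior] / base_mean - 1)), 0.01)
})

test_that("unresolvable oscillation is rejected", {
  expect_error(synthesize_trace(sim_config(step_freq = 40)),
               class = "ldm_config_error")
})

test_that("dropouts and spikes are injected at the configured rates", {
  sim <- synthesize_trace(sim_config(seed = 9, dropout_rate = 0.005,
                                     spike_rate = 0.005))
  expect_gt(sum(!is.finite(sim$trace$d)), 0L)
  cal <- apply_calibration(sim$trace, 7.3)
  mask <- detect_artifacts(cal)
  expect_true(any(mask$cause == "dropout"))
  # truth is unaffected by measurement defects
  clean <- synthesize_trace(sim_config(seed = 9))
  expect_identical(sim$truth$steps, clean$truth$steps)
})

test_that("left-right step-time asymmetry enters with the stated convention", {
  truth <- synthesize_trace(sim_config(seed = 5, asym_step_time = 0.05))$truth
  st <- assign_sides(ground_truth_summary(truth), "L")
  si <- symmetry_index(st, "step_time")
  expect_equal(si$symmetry_index, 5, tolerance = 1e-9)
})
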