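#' Simulator configuration
#'
#' Parameters of the synthetic 100 m sprint generator.  Defaults describe a
#' national-level male sprinter measured by a 100 Hz laser rangefinder:
#' peak speed 11.5 m/s reached with a mono-exponential rise (time constant
#' 1.3 s), mild terminal deceleration over the last 20 m, step frequency
#' 4.5 Hz with a 45% duty factor, a within-step velocity oscillation of
#' +/-0.4 m/s, and Gaussian sensor noise of 20 mm (the device's precision
#' class).
#'
#' @param v_max Asymptotic base speed in m/s (default 11.5).
#' @param tau Acceleration time constant in s (default 1.3).
#' @param race_distance Race length in m (default 100).
#' @param decay_onset Displacement in m where terminal deceleration begins
#'   (default 80).
#' @param decay_rate Fraction of `v_max` lost per 10 m beyond the onset
#'   (default 0.015).
#' @param step_freq Base step frequency in Hz (default 4.5).
#' @param duty_factor Support time as a fraction of step time (default 0.45).
#' @param osc_amplitude Half peak-to-trough of the within-step velocity
#'   oscillation, m/s (default 0.4).
#' @param asym_step_time Signed left-right step-time asymmetry as a
#'   fraction: left step time is `(1 + a/2)` and right `(1 - a/2)` times the
#'   base period, so the classic symmetry index of step time equals
#'   `100 * |a|` percent (default 0).
#' @param asym_amplitude Same convention for the oscillation amplitude
#'   (default 0).
#' @param noise_sd SD of Gaussian sensor noise on distance, m (default 0.020).
#' @param dropout_rate Per-sample probability of starting a beam dropout (a
#'   short run of missing readings); default 0.
#' @param spike_rate Per-sample probability of a one-sample positive
#'   distance spike (beam overshooting the runner); default 0.
#' @param L1 Calibration distance in m added to displacement to form raw
#'   laser distances (default 7.3).
#' @param pre_start_s Seconds of stationary pre-start signal (default 1).
#' @param rate Sampling rate in Hz (default 100).
#' @param first_leg `"L"` or `"R"`: side of the first step (default "L").
#' @param seed Integer seed governing all randomness; `NULL` uses the
#'   current RNG state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(v_max = 11.5, tau = 1.3, race_distance = 100,
                       decay_onset = 80, decay_rate = 0.015,
                       step_freq = 4.5, duty_factor = 0.45,
                       osc_amplitude = 0.4, asym_step_time = 0,
                       asym_amplitude = 0, noise_sd = 0.020,
                       dropout_rate = 0, spike_rate = 0, L1 = 7.3,
                       pre_start_s = 1.0, rate = 100,
                       first_leg = c("L", "R"), seed = NULL) {
  check_scalar_number(v_max, "v_max", lower = 1e-9)
  check_scalar_number(tau, "tau", lower = 1e-9)
  check_scalar_number(race_distance, "race_distance", lower = 1)
  check_scalar_number(decay_onset, "decay_onset", lower = 0)
  check_scalar_number(decay_rate, "decay_rate", lower = 0, upper = 1)
  check_scalar_number(step_freq, "step_freq", lower = 1e-9)
  check_scalar_number(duty_factor, "duty_factor",
                      lower = 1e-9, upper = 1 - 1e-9)
  check_scalar_number(osc_amplitude, "osc_amplitude", lower = 0)
  check_scalar_number(asym_step_time, "asym_step_time", lower = -1, upper = 1)
  check_scalar_number(asym_amplitude, "asym_amplitude", lower = -1, upper = 1)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(dropout_rate, "dropout_rate", lower = 0, upper = 0.5)
  check_scalar_number(spike_rate, "spike_rate", lower = 0, upper = 0.5)
  check_scalar_number(L1, "L1", lower = 1e-9)
  check_scalar_number(pre_start_s, "pre_start_s", lower = 0)
  check_scalar_number(rate, "rate", lower = 1e-9)
  first_leg <- match.arg(first_leg)
  if (!is.null(seed)) check_scalar_number(seed, "seed")
  structure(as.list(environment()), class = "sim_config")
}

#' Base (step-averaged) sprint velocity profile
#'
#' Mono-exponential speed rise `v(t) = v_max * (1 - exp(-t / tau))`,
#' multiplied beyond `decay_onset` by a linearly decreasing factor
#' `1 - decay_rate * (x(t) - decay_onset) / 10` (floored at 0.2) that
#' models terminal deceleration.  `x(t)` here is the undecayed closed-form
#' displacement, which keeps the profile explicit and continuous.
#'
#' @param time Seconds since the start, `>= 0` (vectorized).
#' @param cfg A [sim_config()].
#' @return Base speed in m/s.
#' @examples
#' base_velocity(1.3, sim_config())  # 11.5 * (1 - exp(-1)) = 7.2692
#' @export
base_velocity <- function(time, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  u <- cfg$v_max * (1 - exp(-time / cfg$tau))
  xnd <- displacement_nodecay(time, cfg)
  fac <- pmax(0.2, 1 - cfg$decay_rate * pmax(0, xnd - cfg$decay_onset) / 10)
  u * fac
}

displacement_nodecay <- function(time, cfg) {
  cfg$v_max * (time - cfg$tau * (1 - exp(-time / cfg$tau)))
}

#' Synthesize an LDM sprint trace with ground truth
#'
#' Construction: (1) the base profile [base_velocity()] fixes the
#' step-averaged speed; (2) step cycles are laid down from the start, sides
#' alternating from `cfg$first_leg`, each cycle consisting of a support
#' segment (duration `duty_factor / f`, velocity rising) followed by a
#' flight segment (velocity falling by twice `osc_amplitude`); the rise
#' also carries the cycle's base-speed gain, and each cycle is offset so
#' its mean speed equals the base profile's mean over the same interval —
#' so every touchdown is a true local velocity minimum and every toe-off a
#' true local maximum, as in measured sprint traces; (3) every cycle
#' boundary is recorded as ground truth; (4) velocity is integrated to
#' displacement on a fine internal grid, `pre_start_s` seconds of
#' stationary signal are prepended, the calibration distance `L1` is
#' added, the result is sampled at `rate`, and Gaussian noise, dropouts
#' and spikes are injected.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `ldm_simulation`: list with `trace` (an
#'   [ldm_trace()] of raw laser distances) and `truth` (class
#'   `sim_ground_truth`: start time, event times, per-step table, base
#'   parameters, `v_max` of the base profile, `time_at_race_distance`).
#'   Deterministic for a fixed `cfg$seed`.
#' @export
synthesize_trace <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  T_base <- 1 / cfg$step_freq
  sides_period <- c(L = T_base * (1 + cfg$asym_step_time / 2),
                    R = T_base * (1 - cfg$asym_step_time / 2))
  if (min(sides_period) * cfg$rate < 3) {
    ldm_stop("ldm_config_error",
             "step period (%.4f s) spans fewer than 3 samples at %g Hz",
             min(sides_period), cfg$rate)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  # --- lay down cycles out to a generous horizon past the race distance
  t_r <- stats::uniroot(function(z) displacement_nodecay(z, cfg) -
                          (cfg$race_distance + 2.5),
                        c(1e-6, 1e4 + cfg$race_distance / cfg$v_max * 10))$root
  t_stop <- t_r + 1.5
  side_seq <- character(0)
  td <- 0
  side <- cfg$first_leg
  while (td[length(td)] < t_stop) {
    side_seq <- c(side_seq, side)
    td <- c(td, td[length(td)] + sides_period[[side]])
    side <- if (side == "L") "R" else "L"
  }
  K <- length(side_seq)                 # cycles; touchdowns td[1..K+1]
  Tk <- diff(td)
  Ts <- cfg$duty_factor * Tk
  to <- td[seq_len(K)] + Ts             # toe-off times
  Dk <- 2 * cfg$osc_amplitude *
    (1 + ifelse(side_seq == "L", 1, -1) * cfg$asym_amplitude / 2)

  # --- fine grid including every event time, base profile and cycle gains
  dtf <- 1 / (20 * cfg$rate)
  tf <- sort(unique(c(seq(0, td[K + 1L], by = dtf), td, to)))
  vb_f <- base_velocity(tf, cfg)
  vb_td <- base_velocity(td, cfg)
  gk <- diff(vb_td)
  Rk <- Dk + gk
  # cycle means of the base profile (for the zero-mean offset delta_k)
  cum_vb <- c(0, cumsum(diff(tf) * (vb_f[-1] + vb_f[-length(vb_f)]) / 2))
  cum_at <- stats::approx(tf, cum_vb, xout = td)$y
  mk <- diff(cum_at) / Tk - vb_td[seq_len(K)]
  Tf_seg <- Tk - Ts

  # --- total velocity on the fine grid
  if (all(Dk == 0)) {
    # no oscillation requested: the trace is the pure base profile
    v_f <- vb_f
  } else {
    # Continuous piecewise-linear velocity: cycle k rises from A_k at
    # touchdown to P_k = A_{k+1} + D_k at toe-off, then falls by exactly
    # D_k through flight into A_{k+1}.  The touchdown offsets
    # delta_k = A_k - vb(td_k) solve a forward recursion that makes every
    # cycle's mean speed equal the base profile's mean over that cycle:
    #   m_k = delta_k (1 - c_k) + delta_{k+1} c_k + shape0_k,
    #   c_k = (Ts/2 + Tf)/T,  delta_1 = 0 (start from rest, vb(0) = 0).
    ck <- (Ts / 2 + Tf_seg) / Tk
    shape0 <- (Ts * Rk / 2 + Tf_seg * (Rk + gk) / 2) / Tk
    delta <- numeric(K + 1L)
    for (k in seq_len(K)) {
      delta[k + 1L] <- (mk[k] - shape0[k] - delta[k] * (1 - ck[k])) / ck[k]
    }
    A <- vb_td + delta
    P <- A[-1L] + Dk
    if (any(P <= A[-(K + 1L)])) {
      ldm_stop("ldm_config_error",
               "oscillation amplitude too small for the configured speed rise")
    }
    cyc <- findInterval(tf, td, rightmost.closed = TRUE)
    cyc[cyc > K] <- K
    tau_rel <- tf - td[cyc]
    in_support <- tau_rel <= Ts[cyc]
    v_f <- ifelse(in_support,
                  A[cyc] + (P[cyc] - A[cyc]) * tau_rel / Ts[cyc],
                  P[cyc] - Dk[cyc] * (tau_rel - Ts[cyc]) / Tf_seg[cyc])
  }
  x_f <- c(0, cumsum(diff(tf) * (v_f[-1] + v_f[-length(v_f)]) / 2))

  # --- trim at the first touchdown past race_distance + 2 m
  x_td <- stats::approx(tf, x_f, xout = td)$y
  K_end <- which(x_td >= cfg$race_distance + 2)[1]
  if (is.na(K_end)) K_end <- K + 1L
  t_end <- td[K_end]
  keep <- tf <= t_end + 1e-12

  # --- sample, add the calibration offset and measurement defects
  t_s <- seq(0, cfg$pre_start_s + t_end, by = 1 / cfg$rate)
  run <- t_s >= cfg$pre_start_s
  x_s <- numeric(length(t_s))
  x_s[run] <- stats::approx(tf[keep], x_f[keep],
                            xout = t_s[run] - cfg$pre_start_s, rule = 2)$y
  d <- x_s + cfg$L1
  n <- length(d)
  if (cfg$noise_sd > 0) d <- d + stats::rnorm(n, 0, cfg$noise_sd)
  if (cfg$spike_rate > 0) {
    hit <- which(stats::runif(n) < cfg$spike_rate)
    d[hit] <- d[hit] + stats::runif(length(hit), 1, 3)
  }
  if (cfg$dropout_rate > 0) {
    starts <- which(stats::runif(n) < cfg$dropout_rate)
    for (s in starts) {
      len <- 1L + stats::rgeom(1, 0.3)
      d[s:min(n, s + len - 1L)] <- NaN
    }
  }
  trace <- ldm_trace(t_s, d, nominal_rate = cfg$rate)

  # --- ground truth
  nk <- K_end - 1L
  steps <- data.frame(
    ordinal = seq_len(nk),
    side = side_seq[seq_len(nk)],
    t_touchdown = cfg$pre_start_s + td[seq_len(nk)],
    t_toeoff = cfg$pre_start_s + to[seq_len(nk)],
    t_next_touchdown = cfg$pre_start_s + td[2:(nk + 1L)],
    support_s = Ts[seq_len(nk)],
    flight_s = Tf_seg[seq_len(nk)],
    step_s = Tk[seq_len(nk)],
    length_m = diff(x_td)[seq_len(nk)],
    frequency_hz = 1 / Tk[seq_len(nk)],
    mean_speed = diff(x_td)[seq_len(nk)] / Tk[seq_len(nk)],
    boundary = c(TRUE, rep(FALSE, max(0, nk - 2L)), if (nk > 1L) TRUE),
    stringsAsFactors = FALSE
  )
  t_race <- if (max(x_f[keep]) >= cfg$race_distance) {
    stats::approx(x_f[keep], tf[keep], xout = cfg$race_distance, ties = "ordered")$y
  } else NA_real_
  truth <- structure(list(
    start_time = cfg$pre_start_s,
    touchdown_times = cfg$pre_start_s + td[seq_len(K_end)],
    toeoff_times = cfg$pre_start_s + to[seq_len(nk)],
    steps = steps,
    v_max = max(vb_f[keep]),
    time_at_race_distance = t_race,
    config = cfg
  ), class = "sim_ground_truth")
  structure(list(trace = trace, truth = truth), class = "ldm_simulation")
}

#' @export
print.ldm_simulation <- function(x, ...) {
  cat(sprintf(
    "<ldm_simulation> %d samples, %d steps, base v_max %.2f m/s, %s m in %s s\n",
    length(x$trace$t), nrow(x$truth$steps), x$truth$v_max,
    format(x$truth$config$race_distance),
    if (is.na(x$truth$time_at_race_distance)) "NA"
    else sprintf("%.2f", x$truth$time_at_race_distance)))
  invisible(x)
}

#' Ground-truth step table in the gait-module schema
#'
#' Returns the simulator's per-step truth with exactly the columns produced
#' by [compute_step_metrics()], enabling field-by-field comparison between
#' recovered and true step parameters.
#'
#' @param truth A `sim_ground_truth` (from [synthesize_trace()]).
#' @return A data frame (possibly empty) with the step-table schema.
#' @export
ground_truth_summary <- function(truth) {
  stopifnot(inherits(truth, "sim_ground_truth"))
  truth$steps
}
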