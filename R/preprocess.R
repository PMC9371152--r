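#' Smoothing configuration
#'
#' The analysis uses centered moving-average smoothing throughout, with a
#' default window of `n = 10` samples (0.1 s at 100 Hz).  Different
#' variables need different smoothing: the velocity stream used for peak
#' speed, speed zones and splits is smoothed hard enough to suppress the
#' within-step velocity oscillation (10 passes of the n = 10 window), while
#' the stream used for step detection must keep that oscillation and is
#' only lightly smoothed (see [gait_config()]).
#'
#' @param window_n Window width in samples (default 10).
#' @param passes_m Number of filter passes (default 1).
#' @param displacement,velocity,acceleration,step_metrics Optional
#'   per-variable overrides, each a list with elements `window_n` and/or
#'   `passes_m`.
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(window_n = 10, passes_m = 1,
                             displacement = NULL, velocity = NULL,
                             acceleration = NULL, step_metrics = NULL) {
  check_scalar_number(window_n, "window_n", lower = 1)
  check_scalar_number(passes_m, "passes_m", lower = 1)
  ov <- function(x) {
    if (is.null(x)) return(NULL)
    stopifnot(is.list(x))
    x
  }
  structure(list(window_n = as.integer(window_n),
                 passes_m = as.integer(passes_m),
                 displacement = ov(displacement), velocity = ov(velocity),
                 acceleration = ov(acceleration),
                 step_metrics = ov(step_metrics)),
            class = "smoothing_config")
}

smoothing_for <- function(cfg, variable) {
  ov <- cfg[[variable]]
  list(window_n = if (!is.null(ov$window_n)) ov$window_n else cfg$window_n,
       passes_m = if (!is.null(ov$passes_m)) ov$passes_m else cfg$passes_m)
}

#' Start/end detection configuration
#'
#' @param k_sd Multiplier on the pre-start noise SD for the start threshold
#'   (default 2).
#' @param pre_window Seconds of assumed pre-start signal used to estimate
#'   the noise level (default 1).
#' @param min_threshold Floor for the start threshold in meters (default
#'   0.01); guards the degenerate noise-free case where the pre-start SD
#'   is zero.
#' @param hold Seconds the displacement must remain above threshold for the
#'   crossing to count as the start (default 0.1, one smoothing window).
#' @param end_distance Displacement in meters whose crossing triggers the
#'   end rule (default 60).
#' @param end_extra_points Samples appended after the end crossing
#'   (default 50).
#' @param crop_pad Seconds of data kept before the start and after the end
#'   when cropping (default 1).
#' @param rezero_time If `TRUE` (default), [crop_trace()] shifts the time
#'   axis so the detected start is at `t = 0`.
#' @return An object of class `start_end_config`.
#' @export
start_end_config <- function(k_sd = 2, pre_window = 1.0, min_threshold = 0.01,
                             hold = 0.1, end_distance = 60,
                             end_extra_points = 50, crop_pad = 1.0,
                             rezero_time = TRUE) {
  check_scalar_number(k_sd, "k_sd", lower = 1e-9)
  check_scalar_number(pre_window, "pre_window", lower = 0)
  check_scalar_number(min_threshold, "min_threshold", lower = 0)
  check_scalar_number(hold, "hold", lower = 0)
  check_scalar_number(end_distance, "end_distance", lower = 1e-9)
  check_scalar_number(end_extra_points, "end_extra_points", lower = 0)
  check_scalar_number(crop_pad, "crop_pad", lower = 0)
  structure(list(k_sd = k_sd, pre_window = pre_window,
                 min_threshold = min_threshold, hold = hold,
                 end_distance = end_distance,
                 end_extra_points = as.integer(end_extra_points),
                 crop_pad = crop_pad, rezero_time = isTRUE(rezero_time)),
            class = "start_end_config")
}

#' Centered moving-average smoother
#'
#' Windowed mean with the window centered on each sample and clipped at the
#' array edges (edge outputs average over the available samples only), so
#' the output has the same length as the input and no phase lag.  For an
#' even window `n` the window covers offsets `-(n/2 - 1) ... n/2`.
#' At 100 Hz the default analysis window of `n = 10` spans 0.1 s.
#'
#' @param y Numeric vector.
#' @param window_n Window width in samples (`>= 1`).
#' @param passes_m Number of repeated applications (default 1).
#' @return Smoothed vector, same length as `y`.
#' @examples
#' moving_average(c(0, 1, 2, 3, 4), 3)  # 0.5 1 2 3 3.5
#' @export
moving_average <- function(y, window_n, passes_m = 1) {
  if (!is.numeric(window_n) || length(window_n) != 1L || !is.finite(window_n) ||
      window_n < 1) {
    ldm_stop("ldm_config_error", "window_n must be a single number >= 1")
  }
  check_scalar_number(passes_m, "passes_m", lower = 1)
  n <- as.integer(window_n)
  N <- length(y)
  if (N == 0L) ldm_stop("ldm_config_error", "empty input")
  if (n == 1L || N == 1L) return(as.double(y))
  lo <- (n - 1L) %/% 2L
  hi <- n %/% 2L
  i <- seq_len(N)
  j0 <- pmax(i - lo, 1L)
  j1 <- pmin(i + hi, N)
  for (p in seq_len(passes_m)) {
    cs <- c(0, cumsum(as.double(y)))
    y <- (cs[j1 + 1L] - cs[j0]) / (j1 - j0 + 1L)
  }
  y
}

#' Detect measurement artifacts in a calibrated trace
#'
#' Flags two kinds of defects typical of laser tracking: dropouts (the beam
#' lost the runner; readings are missing) and spikes (the beam momentarily
#' caught an arm, another person, or the background; the implied
#' point-to-point speed is physically impossible).  A sample is flagged as
#' a spike when the one-step speed `|dx/dt|` both into and out of it
#' exceeds `vmax_phys`.  Consecutive flagged samples merge into segments;
#' segments touching the first or last sample are labeled `"edge"`.
#'
#' @param trace An `ldm_calibrated` trace.
#' @param vmax_phys Physically plausible speed ceiling in m/s (default 13;
#'   elite sprinters top out near 12.5 m/s).
#' @return A data frame of class `artifact_mask` with columns `start`,
#'   `end` (1-based inclusive sample indices) and `cause`
#'   (`"dropout"`, `"spike"` or `"edge"`).  Zero rows if the trace is clean.
#' @export
detect_artifacts <- function(trace, vmax_phys = 13) {
  stopifnot(inherits(trace, "ldm_calibrated"))
  check_scalar_number(vmax_phys, "vmax_phys", lower = 1e-9)
  x <- trace$x
  t <- trace$t
  N <- length(x)
  bad <- !is.finite(x)
  # spike scan: one-step speeds between finite neighbours
  if (N >= 3L) {
    sp <- abs(diff(x) / diff(t))          # length N-1, NA across dropouts
    excess <- is.finite(sp) & sp > vmax_phys
    # a run of excessive increments from j0..j1 brackets samples j0+1..j1
    r <- rle(excess)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 2L)) {
      bad[(starts[k] + 1L):ends[k]] <- TRUE
    }
  }
  seg <- mask_from_flags(bad, N)
  if (nrow(seg)) {
    dropout <- vapply(seq_len(nrow(seg)), function(i) {
      any(!is.finite(x[seg$start[i]:seg$end[i]]))
    }, logical(1))
    seg$cause <- ifelse(dropout, "dropout", "spike")
    seg$cause[seg$start == 1L | seg$end == N] <- "edge"
  }
  structure(seg, class = c("artifact_mask", "data.frame"))
}

mask_from_flags <- function(bad, N) {
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             cause = character(sum(keep)), stringsAsFactors = FALSE)
}

#' Repair flagged artifacts
#'
#' Interior flagged segments are replaced by linear interpolation between
#' the nearest clean neighbors.  Segments touching the first or last sample
#' have no clean anchor on one side and are cropped off instead of
#' extrapolated.
#'
#' @param trace An `ldm_calibrated` trace.
#' @param mask An `artifact_mask` from [detect_artifacts()].
#' @return A repaired `ldm_calibrated` trace.  Unflagged samples are
#'   bit-identical to the input.
#' @export
repair_artifacts <- function(trace, mask) {
  stopifnot(inherits(trace, "ldm_calibrated"))
  N <- length(trace$x)
  if (nrow(mask) == 0L) return(trace)
  if (any(mask$start < 1L | mask$end > N | mask$start > mask$end)) {
    ldm_stop("ldm_repair_error", "mask segments out of trace bounds")
  }
  bad <- rep(FALSE, N)
  for (i in seq_len(nrow(mask))) bad[mask$start[i]:mask$end[i]] <- TRUE
  if (all(bad)) {
    ldm_stop("ldm_repair_error", "mask covers the entire trace")
  }
  keep_range <- range(which(!bad))
  out <- trace
  interior_bad <- bad
  interior_bad[seq_len(N) < keep_range[1] | seq_len(N) > keep_range[2]] <- FALSE
  if (any(interior_bad)) {
    good <- !bad
    out$x[interior_bad] <- stats::approx(trace$t[good], trace$x[good],
                                         xout = trace$t[interior_bad])$y
  }
  if (keep_range[1] > 1L || keep_range[2] < N) {
    idx <- keep_range[1]:keep_range[2]
    out$t <- out$t[idx]
    out$x <- out$x[idx]
  }
  out
}

#' Detect the sprint start
#'
#' The start is found on the raw displacement: the noise level of the
#' stationary pre-start signal is estimated over the first `pre_window`
#' seconds, and the start is the first sample whose displacement rises
#' above `mean_pre + max(k_sd * sd_pre, min_threshold)` and remains above
#' it for a full hold window (default 0.1 s).  The hold operationalizes
#' "increased and remained above"; it is evaluated on the 0.1 s
#' moving-average trend of the displacement, so that individual noisy
#' samples dipping through the threshold neither delay the start nor
#' trigger it early.
#'
#' @param trace An `ldm_calibrated` trace (artifact-repaired).
#' @param cfg A [start_end_config()].
#' @return The 1-based index of the start sample, with attributes
#'   `threshold`, `mean_pre` and `sd_pre`.
#' @export
detect_start <- function(trace, cfg = start_end_config()) {
  stopifnot(inherits(trace, "ldm_calibrated"),
            inherits(cfg, "start_end_config"))
  t <- trace$t
  x <- trace$x
  pre <- which(t < t[1] + cfg$pre_window)
  if (length(pre) < 2L || length(pre) >= length(t)) {
    ldm_stop("ldm_config_error",
             "pre_window (%g s) must cover >= 2 samples and less than the trace",
             cfg$pre_window)
  }
  mean_pre <- mean(x[pre])
  sd_pre <- stats::sd(x[pre])
  thr <- mean_pre + max(cfg$k_sd * sd_pre, cfg$min_threshold)
  hold_n <- max(1L, as.integer(round(cfg$hold * trace$nominal_rate)))
  N <- length(x)
  above <- x > thr
  above[!is.finite(x)] <- FALSE
  x_trend <- moving_average(ifelse(is.finite(x), x, mean_pre),
                            max(1L, as.integer(round(0.1 * trace$nominal_rate))))
  held <- x_trend > thr
  # first crossing sample from which the hold condition is met for
  # hold_n consecutive samples
  bad_cum <- c(0L, cumsum(!held))
  cand <- which(above)
  cand <- cand[cand + hold_n - 1L <= N]
  cand <- cand[bad_cum[cand + hold_n] - bad_cum[cand] == 0L]
  if (length(cand) == 0L) {
    ldm_stop("ldm_no_start_error",
             "displacement never exceeds the start threshold (%.3f m) for %d samples",
             thr, hold_n)
  }
  structure(cand[1], threshold = thr, mean_pre = mean_pre, sd_pre = sd_pre)
}

#' Detect the sprint end
#'
#' End rule: the endpoint is a fixed number of samples (default 50) after
#' the displacement first exceeds `end_distance` (default 60 m), clipped to
#' the last sample.
#'
#' @inheritParams detect_start
#' @return The 1-based index of the end sample.
#' @export
detect_end <- function(trace, cfg = start_end_config()) {
  stopifnot(inherits(trace, "ldm_calibrated"),
            inherits(cfg, "start_end_config"))
  over <- which(trace$x > cfg$end_distance)
  if (length(over) == 0L) {
    ldm_stop("ldm_end_not_reached_error",
             "displacement never exceeds %g m (max %.2f m)",
             cfg$end_distance, max(trace$x, na.rm = TRUE))
  }
  min(over[1] + cfg$end_extra_points, length(trace$x))
}

#' Crop a trace to the detected run
#'
#' Keeps `crop_pad` seconds of context before the start and after the end
#' (clipped to the trace bounds) and, when `cfg$rezero_time` is `TRUE`,
#' shifts the time axis so the detected start sample is at `t = 0`.
#'
#' @param trace An `ldm_calibrated` trace.
#' @param start,end 1-based start/end sample indices
#'   (from [detect_start()] / [detect_end()]).
#' @param cfg A [start_end_config()].
#' @return The cropped `ldm_calibrated` trace with attributes
#'   `start_index` (index of the start sample within the cropped trace) and
#'   `t_start` (original time of the start sample).
#' @export
crop_trace <- function(trace, start, end, cfg = start_end_config()) {
  stopifnot(inherits(trace, "ldm_calibrated"))
  start <- as.integer(start)
  end <- as.integer(end)
  N <- length(trace$x)
  if (start >= end) {
    ldm_stop("ldm_config_error", "start (%d) must precede end (%d)", start, end)
  }
  if (start < 1L || end > N) {
    ldm_stop("ldm_config_error", "start/end outside trace bounds")
  }
  pad <- as.integer(round(cfg$crop_pad * trace$nominal_rate))
  i0 <- max(1L, start - pad)
  i1 <- min(N, end + pad)
  out <- trace
  out$t <- trace$t[i0:i1]
  out$x <- trace$x[i0:i1]
  t_start <- trace$t[start]
  if (cfg$rezero_time) out$t <- out$t - t_start
  attr(out, "start_index") <- start - i0 + 1L
  attr(out, "t_start") <- t_start
  out
}

#' Locate the instant of first motion by a crease fit
#'
#' The threshold rule of [detect_start()] fires a few samples after motion
#' actually begins (displacement must clear the noise threshold and hold).
#' For timing purposes the instant the athlete leaves the line is better
#' estimated by fitting `x = a + c * max(t - beta, 0)^2` — flat pre-start
#' signal followed by a quadratic rise through the first support phase —
#' around the detected start, and taking the breakpoint `beta`.  Exact on
#' noise-free traces; least-squares optimal under white sensor noise.
#'
#' @param trace An `ldm_calibrated` trace.
#' @param start_index Index from [detect_start()] (in `trace`'s frame).
#' @param left_s Fit window extent in seconds before the detected start
#'   (default 0.5).
#' @param right_x Right window edge: the fit uses samples up to the first
#'   displacement exceeding this many meters (default 0.5 m — the early
#'   rise is close to one smooth push and carries high signal-to-noise).
#' @return Estimated onset time (same time axis as `trace$t`), clamped to
#'   at most 0.15 s before and 0.02 s after the threshold-rule start.
#' @export
locate_onset <- function(trace, start_index, left_s = 0.3, right_s = 0.15) {
  t <- trace$t
  x <- trace$x
  n <- length(t)
  h <- 1 / trace$nominal_rate
  marg <- 4L
  n_s <- 5L                              # light smoothing inside the fit
  j0 <- max(1L, start_index - as.integer(round(left_s / h)) - marg)
  j1 <- min(n, start_index + as.integer(round(right_s / h)) + marg)
  if (j1 - j0 + 1L < 12L + 2L * marg) return(t[start_index])
  tte <- t[j0:j1] - t[start_index]
  keep <- seq_along(tte) > marg & seq_along(tte) <= length(tte) - marg
  xs <- moving_average(x[j0:j1], n_s)[keep]
  tt <- tte[keep]
  # model: flat pre-start, then the first support (one quadratic starting
  # at the onset beta), then flight (a second quadratic switched on at
  # beta + s); beta and the support duration s are grid-searched, the
  # amplitudes are linear.  Model columns pass through the same light
  # smoother as the data, so the fit stays exact on noise-free traces.
  col <- function(raw) moving_average(raw, n_s)[keep]
  sse_at <- function(beta, s) {
    X <- cbind(1,
               col(ifelse(tte > beta, (tte - beta)^2, 0)),
               col(ifelse(tte > beta + s, (tte - beta - s)^2, 0)))
    sum(stats::.lm.fit(X, xs)$residuals^2)
  }
  cand_b <- seq(max(tt[3], -0.12), min(0.01, tt[length(tt) - 3L]), by = h)
  cand_s <- seq(0.05, 0.14, by = 0.01)
  best <- c(Inf, NA, NA)
  for (beta in cand_b) {
    for (s in cand_s) {
      r2 <- sse_at(beta, s)
      if (r2 < best[1]) best <- c(r2, beta, s)
    }
  }
  beta <- best[2]
  if (is.na(beta)) return(t[start_index])
  # parabolic sub-sample refinement in beta at the selected s
  s <- best[3]
  s1 <- sse_at(beta - h, s); s3 <- sse_at(beta + h, s)
  den <- s1 - 2 * best[1] + s3
  if (is.finite(den) && den > 0) {
    beta <- beta + max(-1, min(1, 0.5 * (s1 - s3) / den)) * h
  }
  t[start_index] + max(min(beta, 0.02), -0.15)
}

#' Export an artifact mask as CSV
#'
#' @param mask An `artifact_mask`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.csv(as.data.frame(mask), path, row.names = FALSE)
  invisible(path)
}
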