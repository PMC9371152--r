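#' Differentiate displacement into velocity
#'
#' Central differences at interior points,
#' `v_i = (x_{i+1} - x_{i-1}) / (t_{i+1} - t_{i-1})`, one-sided differences
#' at the two ends.  Actual sample times are used throughout, so moderate
#' sampling jitter is handled correctly.  Central differencing is exact for
#' displacement that is polynomial of degree <= 2 and has an `O(h^2)`
#' truncation error otherwise (about `2e-5` m/s for a sinusoid at 100 Hz).
#'
#' @param t Sample times in seconds, strictly increasing, length `>= 3`.
#' @param x Displacement in meters, same length.
#' @return Velocity in m/s, same length as `x`.
#' @export
compute_velocity <- function(t, x) {
  central_difference(t, x, "displacement")
}

#' Differentiate velocity into acceleration
#'
#' Linear acceleration is the change of speed over time, evaluated with the
#' same symmetric stencil as [compute_velocity()]:
#' `a_i = (v_{i+1} - v_{i-1}) / (t_{i+1} - t_{i-1})` at interior points,
#' one-sided at the ends.
#'
#' @param t Sample times in seconds, strictly increasing, length `>= 3`.
#' @param v Velocity in m/s, same length.
#' @return Acceleration in m/s^2, same length as `v`.
#' @export
compute_acceleration <- function(t, v) {
  central_difference(t, v, "velocity")
}

central_difference <- function(t, y, what) {
  n <- length(y)
  if (n < 3L || length(t) != n) {
    ldm_stop("ldm_compute_error",
             "need at least 3 %s samples (got %d)", what, n)
  }
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  d
}

#' Build the kinematic series for a cropped run
#'
#' Produces the aligned time/displacement/velocity/acceleration arrays used
#' by all downstream analyses.  Two velocity streams are kept on purpose:
#' `v_smooth` (default: 10 passes of the n = 10 moving average) suppresses
#' the within-step velocity oscillation and feeds peak speed, speed zones
#' and splits; `v_raw` (differenced from the lightly smoothed displacement)
#' keeps the oscillation that step detection needs.
#'
#' @param trace A cropped `ldm_calibrated` trace.
#' @param smoothing A [smoothing_config()].  Per-variable overrides:
#'   `displacement` smooths `x` before differencing (default window 10,
#'   1 pass); `velocity` controls `v_smooth` (default window 10,
#'   10 passes); `acceleration` controls `a_smooth` (defaults to the
#'   velocity setting).
#' @return An object of class `kinematic_series`: list with `t`, `x`
#'   (analysis displacement), `x_raw`, `v_raw`, `v_smooth`, `a_raw`,
#'   `a_smooth`, `smoothing`, `nominal_rate`.
#' @export
kinematic_series <- function(trace, smoothing = default_smoothing()) {
  stopifnot(inherits(trace, "ldm_calibrated"),
            inherits(smoothing, "smoothing_config"))
  sx <- smoothing_for(smoothing, "displacement")
  sv <- smoothing_for(smoothing, "velocity")
  sa <- smoothing_for(smoothing, "acceleration")
  x <- moving_average(trace$x, sx$window_n, sx$passes_m)
  v_raw <- compute_velocity(trace$t, x)
  v_smooth <- moving_average(v_raw, sv$window_n, sv$passes_m)
  a_raw <- compute_acceleration(trace$t, v_raw)
  a_smooth <- compute_acceleration(trace$t, v_smooth)
  a_smooth <- moving_average(a_smooth, sa$window_n, sa$passes_m)
  structure(list(t = trace$t, x = x, x_raw = trace$x, v_raw = v_raw,
                 v_smooth = v_smooth, a_raw = a_raw, a_smooth = a_smooth,
                 smoothing = smoothing, nominal_rate = trace$nominal_rate,
                 start_index = attr(trace, "start_index")),
            class = "kinematic_series")
}

#' Default per-variable smoothing
#'
#' Displacement: n = 10, 1 pass (takes the edge off sensor noise without
#' flattening the step oscillation).  Velocity: n = 10, 10 passes — at
#' 100 Hz ten passes of the 0.1 s window attenuate a 4.5 Hz step
#' oscillation by a factor of about 30, which is what peak-speed and
#' zone estimation need.
#'
#' @return A [smoothing_config()].
#' @export
default_smoothing <- function() {
  smoothing_config(window_n = 10, passes_m = 1,
                   displacement = list(window_n = 10, passes_m = 1),
                   velocity = list(window_n = 10, passes_m = 10),
                   acceleration = list(window_n = 10, passes_m = 10))
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf(
    "<kinematic_series> %d samples, t = [%.2f, %.2f] s, peak v_smooth = %.2f m/s\n",
    length(x$t), x$t[1], x$t[length(x$t)], max(x$v_smooth)))
  invisible(x)
}

#' Segment a run into speed zones
#'
#' Every sprint shows three contiguous phases: ascending speed, maintenance
#' of the maximum speed, and descending speed.  The maintenance zone is
#' defined by a tolerance (default 2%) below the peak of the smoothed speed
#' curve: it spans from the first to the last sample with
#' `v >= (1 - tolerance) * v_max`.  Interior dips below the threshold stay
#' inside the maintenance zone, so the three zones are contiguous and
#' partition the run.
#'
#' @param v_smooth Smoothed velocity in m/s (within-step oscillation
#'   suppressed).
#' @param tolerance Fraction of peak speed (default 0.02), in `(0, 0.5)`.
#' @return An object of class `speed_zones`: list with `ascending`,
#'   `maintenance`, `descending` (each `c(first, last)` 1-based inclusive
#'   index range, or `NULL` when empty), `tolerance`, `v_max`, `i_vmax`
#'   (first index attaining the maximum), `threshold`.
#' @export
segment_zones <- function(v_smooth, tolerance = 0.02) {
  if (length(v_smooth) == 0L) {
    ldm_stop("ldm_compute_error", "empty velocity array")
  }
  check_scalar_number(tolerance, "tolerance", lower = 1e-12,
                      upper = 0.5 - 1e-12)
  v_max <- max(v_smooth)
  i_vmax <- which.max(v_smooth)
  # tolerance band below the peak; |v_max| keeps the band non-empty for
  # signals that never go positive (degenerate but must not crash)
  thr <- v_max - tolerance * abs(v_max)
  inzone <- which(v_smooth >= thr | seq_along(v_smooth) == i_vmax)
  m0 <- inzone[1]
  m1 <- inzone[length(inzone)]
  n <- length(v_smooth)
  rng <- function(a, b) if (a > b) NULL else c(a, b)
  structure(list(
    ascending = rng(1L, m0 - 1L),
    maintenance = rng(m0, m1),
    descending = rng(m1 + 1L, n),
    tolerance = tolerance, v_max = v_max, i_vmax = i_vmax, threshold = thr,
    n = n
  ), class = "speed_zones")
}

#' @export
print.speed_zones <- function(x, ...) {
  fmt <- function(r) if (is.null(r)) "-" else sprintf("[%d, %d]", r[1], r[2])
  cat(sprintf(
    "<speed_zones> v_max = %.3f m/s (tol %g%%): ascending %s, maintenance %s, descending %s\n",
    x$v_max, 100 * x$tolerance, fmt(x$ascending), fmt(x$maintenance),
    fmt(x$descending)))
  invisible(x)
}

#' Summarize speed zones in time and distance coordinates
#'
#' @param zones A `speed_zones` object.
#' @param t,x,v_smooth The aligned arrays the zones were computed from.
#' @return A data frame with one row per non-empty zone: `zone`, `t_from`,
#'   `t_to`, `duration_s`, `x_from_m`, `x_to_m`, `distance_m`,
#'   `mean_speed`, `max_speed`.
#' @export
zone_table <- function(zones, t, x, v_smooth) {
  stopifnot(inherits(zones, "speed_zones"))
  rows <- lapply(c("ascending", "maintenance", "descending"), function(z) {
    r <- zones[[z]]
    if (is.null(r)) return(NULL)
    i <- r[1]:r[2]
    data.frame(zone = z, t_from = t[r[1]], t_to = t[r[2]],
               duration_s = t[r[2]] - t[r[1]],
               x_from_m = x[r[1]], x_to_m = x[r[2]],
               distance_m = x[r[2]] - x[r[1]],
               mean_speed = mean(v_smooth[i]),
               max_speed = max(v_smooth[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split a run into fixed-length sections
#'
#' Splits the race distance into sections (default ten 10 m sections of a
#' 100 m run).  The crossing time of each section boundary is found by
#' linear interpolation of displacement between the two bracketing samples,
#' never snapped to the sample grid.  The time origin is the interpolated
#' crossing of `x = 0` (the start line), searched backward from the first
#' sustained rise so that pre-start noise cannot trigger it.
#'
#' @param t Time in seconds (cropped run, any origin).
#' @param x Analysis displacement in meters (should include a sample at or
#'   below 0 before the run).
#' @param v_smooth Smoothed velocity, aligned with `t`.
#' @param section_len Section length in meters (default 10).
#' @param total Total distance in meters (default 100).
#' @param t0 Optional externally determined time of the start-line
#'   crossing (e.g. from [locate_onset()]); when `NULL` it is interpolated
#'   from the displacement like every other boundary.
#' @return A data frame of class `section_splits`: `section_from_m`,
#'   `section_to_m`, `split_s`, `cumulative_s`, `mean_speed`, `max_speed`,
#'   `partial`.  The final section is flagged `partial = TRUE` when the
#'   trace ends before its far boundary (its `split_s`/`mean_speed` are
#'   `NA`, `max_speed` covers the observed part).
#' @export
section_splits <- function(t, x, v_smooth, section_len = 10, total = 100,
                           t0 = NULL) {
  check_scalar_number(section_len, "section_len", lower = 1e-9)
  check_scalar_number(total, "total", lower = section_len)
  if (max(x) < section_len) {
    ldm_stop("ldm_compute_error",
             "trace covers %.1f m, less than one %g m section", max(x),
             section_len)
  }
  bounds <- seq(0, total, by = section_len)
  tb <- boundary_times(t, x, bounds)
  if (!is.null(t0)) tb[1] <- t0
  if (is.na(tb[1])) {
    ldm_stop("ldm_compute_error",
             "cannot locate the start-line crossing (x = 0); trace must begin at or before the start line")
  }
  n_complete <- sum(!is.na(tb)) - 1L
  if (n_complete < 1L) {
    ldm_stop("ldm_compute_error", "no complete section in trace")
  }
  res <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    from <- bounds[k]
    to <- bounds[k + 1L]
    if (!is.na(tb[k + 1L])) {
      split <- tb[k + 1L] - tb[k]
      in_sec <- x >= from & x < to
      res[[k]] <- data.frame(
        section_from_m = from, section_to_m = to, split_s = split,
        cumulative_s = tb[k + 1L] - tb[1L],
        mean_speed = section_len / split,
        max_speed = if (any(in_sec)) max(v_smooth[in_sec]) else NA_real_,
        partial = FALSE)
    } else if (!is.na(tb[k]) && max(x) > from) {
      in_sec <- x >= from & x < to
      res[[k]] <- data.frame(
        section_from_m = from, section_to_m = to, split_s = NA_real_,
        cumulative_s = NA_real_, mean_speed = NA_real_,
        max_speed = if (any(in_sec)) max(v_smooth[in_sec]) else NA_real_,
        partial = TRUE)
      break
    } else break
  }
  out <- do.call(rbind, res)
  class(out) <- c("section_splits", "data.frame")
  out
}

# Interpolated crossing times of each displacement boundary.  For each
# boundary b: find the first index at which x exceeds b and stays above it
# for a short hold (robust to noise wiggle), then walk back to the last
# sample with x <= b and interpolate the crossing inside that interval.
boundary_times <- function(t, x, bounds, hold_n = 5L) {
  n <- length(x)
  vapply(bounds, function(b) {
    above <- x > b
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & (r$lengths >= hold_n | ends == n)
    if (!any(ok)) return(NA_real_)
    i_up <- starts[ok][1]
    j <- i_up - 1L
    while (j >= 1L && x[j] > b) j <- j - 1L   # last sample at or below b
    if (j < 1L) return(NA_real_)
    # linear interpolation between j and the next sample above b
    jj <- j + 1L
    if (x[jj] == x[j]) return(t[jj])
    t[j] + (b - x[j]) * (t[jj] - t[j]) / (x[jj] - x[j])
  }, numeric(1))
}
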