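#' Analyze one sprint trace end to end
#'
#' Runs the full processing chain on a raw LDM trace: calibration (x = d -
#' L1), artifact detection and repair, start/end detection, cropping with
#' time re-zeroed at the start, kinematics (two velocity streams), speed
#' zones, 10 m section splits, step-event detection with crease
#' refinement, step metrics, side assignment, symmetry, and report
#' assembly.  Stages that cannot run on a given trace (e.g. splits on a
#' run shorter than one section, symmetry with unknown sides) are skipped
#' and recorded in the report provenance rather than failing the whole
#' analysis.
#'
#' @param trace An [ldm_trace()] of raw laser distances.
#' @param meta A [measurement_meta()] (supplies `L1`, the zone tolerance
#'   and the starting leg).
#' @param start_end A [start_end_config()].
#' @param smoothing A [smoothing_config()] (default [default_smoothing()]).
#' @param gait A [gait_config()].
#' @param section_len,total Section length and race distance for splits
#'   (defaults 10 and `meta$measured_distance`).
#' @param vmax_phys Artifact speed ceiling in m/s (default 13).
#' @param seed Optional seed recorded in provenance (simulated inputs).
#' @return An object of class `sprint_analysis`: list with `trace`
#'   (cropped, repaired), `mask`, `start_index`, `end_index`, `kin`,
#'   `zones`, `zone_summary`, `splits`, `events`, `steps`, `symmetry`,
#'   `report`.
#' @examples
#' sim <- synthesize_trace(sim_config(seed = 1))
#' meta <- measurement_meta(calibration_distance_L1 = 7.3,
#'                          first_leg_on_start = "L")
#' res <- analyze_sprint(sim$trace, meta,
#'                       start_end = start_end_config(end_distance = 95))
#' res$zones
#' @export
analyze_sprint <- function(trace, meta,
                           start_end = start_end_config(),
                           smoothing = default_smoothing(),
                           gait = gait_config(),
                           section_len = 10, total = NULL,
                           vmax_phys = 13, seed = NULL) {
  stopifnot(inherits(trace, "ldm_trace"), inherits(meta, "measurement_meta"))
  if (is.null(total)) total <- meta$measured_distance

  cal <- apply_calibration(trace, meta$calibration_distance_L1)
  cal$meta <- meta
  mask <- detect_artifacts(cal, vmax_phys = vmax_phys)
  rep_tr <- repair_artifacts(cal, mask)

  i_start <- detect_start(rep_tr, start_end)
  i_end <- detect_end(rep_tr, start_end)
  run <- crop_trace(rep_tr, i_start, i_end, start_end)

  kin <- kinematic_series(run, smoothing)
  zones <- segment_zones(kin$v_smooth, meta$max_speed_tolerance)
  zsum <- zone_table(zones, kin$t, kin$x, kin$v_smooth)

  t0 <- locate_onset(run, attr(run, "start_index"))
  splits <- tryCatch(
    section_splits(kin$t, run$x, kin$v_smooth, section_len = section_len,
                   total = total, t0 = t0),
    ldm_compute_error = function(e) NULL)

  v_det <- detection_velocity(run, gait)
  # first ground contact seeded at the crease-fit onset, which is unbiased
  # (the threshold-rule start index fires a few samples late)
  start_in_run <- which.min(abs(run$t - t0))
  gait_res <- tryCatch({
    events <- detect_step_events(run$t, v_det, gait,
                                 first_touchdown = start_in_run)
    if (gait$refine) {
      events <- refine_step_events(events, run$t, run$x, gait)
    }
    steps <- compute_step_metrics(events, run$t, run$x, v_det,
                                  convention = gait$boundary_convention)
    steps <- assign_sides(steps, meta$first_leg_on_start)
    list(events = events, steps = steps)
  }, ldm_no_steps_error = function(e) list(events = NULL, steps = NULL))

  symmetry <- NULL
  if (!is.null(gait_res$steps) &&
      all(c("L", "R") %in% gait_res$steps$side)) {
    symmetry <- lapply(c("speed", "step_length", "support_time",
                         "flight_time", "step_frequency", "step_time"),
                       function(v) {
                         tryCatch(symmetry_index(gait_res$steps, v),
                                  ldm_symmetry_unavailable_error =
                                    function(e) NULL)
                       })
    symmetry <- Filter(Negate(is.null), symmetry)
    if (length(symmetry) == 0L) symmetry <- NULL
  }

  report <- build_report(kin, zones = zones, zone_summary = zsum,
                         splits = splits, steps = gait_res$steps,
                         symmetry = symmetry, meta = meta, mask = mask,
                         configs = list(start_end = start_end,
                                        smoothing = smoothing, gait = gait),
                         seed = seed)
  structure(list(trace = run, mask = mask, start_index = i_start,
                 end_index = i_end, kin = kin, zones = zones,
                 zone_summary = zsum, splits = splits,
                 events = gait_res$events, steps = gait_res$steps,
                 symmetry = symmetry, report = report),
            class = "sprint_analysis")
}

#' @export
print.sprint_analysis <- function(x, ...) {
  cat("<sprint_analysis>\n")
  cat(sprintf("  run: %.2f m in %.2f s, peak speed %.2f m/s\n",
              max(x$kin$x), x$kin$t[length(x$kin$t)] - x$kin$t[1],
              x$zones$v_max))
  if (!is.null(x$splits)) {
    done <- x$splits[!x$splits$partial, ]
    cat(sprintf("  splits: %d complete sections, cumulative %.2f s at %g m\n",
                nrow(done), done$cumulative_s[nrow(done)],
                done$section_to_m[nrow(done)]))
  }
  if (!is.null(x$steps)) {
    cat(sprintf("  steps: %d detected, mean step time %.3f s, mean length %.2f m\n",
                nrow(x$steps), mean(x$steps$step_s[!x$steps$boundary]),
                mean(x$steps$length_m[!x$steps$boundary])))
  }
  if (!is.null(x$symmetry)) {
    st <- do.call(rbind, x$symmetry)
    cat(sprintf("  symmetry index: %s\n",
                paste(sprintf("%s %.2f%%", st$variable, st$symmetry_index),
                      collapse = ", ")))
  }
  invisible(x)
}
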