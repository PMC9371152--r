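#' Descriptive statistics of a variable
#'
#' Mean, median, mode, minimum, maximum, sample standard deviation
#' (divisor n - 1), skewness and excess kurtosis.  The mode of continuous
#' data is the most frequent value after rounding to `mode_digits` decimals
#' (raw floats almost never repeat), with ties broken by the smallest
#' value.  Skewness and kurtosis use the standard moment formulas
#' `g1 = m3 / m2^(3/2)` and `g2 = m4 / m2^2 - 3` (central moments with
#' divisor n); they are `NA` for n < 3 / n < 4 or zero variance.  A single
#' value gets `sd = 0` by convention, flagged via the `degenerate` field.
#'
#' @param values Numeric vector, length `>= 1`, `NA`s removed.
#' @param mode_digits Rounding used for the mode (default 2).
#' @return An object of class `descriptive_stats`: list with `n`, `mean`,
#'   `median`, `mode`, `minimum`, `maximum`, `sd`, `skewness`, `kurtosis`,
#'   `degenerate`.
#' @examples
#' descriptive_stats(c(2, 2, 3, 5))  # mean 3, median 2.5, mode 2, sd 1.414
#' @export
descriptive_stats <- function(values, mode_digits = 2) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) ldm_stop("ldm_stats_error", "empty input")
  r <- round(values, mode_digits)
  tab <- table(r)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  s <- if (n >= 2L) stats::sd(values) else 0
  m2 <- mean((values - mean(values))^2)
  skew <- if (n >= 3L && m2 > 0) mean((values - mean(values))^3) / m2^1.5
          else NA_real_
  kurt <- if (n >= 4L && m2 > 0) mean((values - mean(values))^4) / m2^2 - 3
          else NA_real_
  structure(list(n = n, mean = mean(values), median = stats::median(values),
                 mode = min(modes), minimum = min(values),
                 maximum = max(values), sd = s, skewness = skew,
                 kurtosis = kurt, degenerate = n < 2L || s == 0),
            class = "descriptive_stats")
}

#' @export
print.descriptive_stats <- function(x, ...) {
  cat(sprintf(
    "<descriptive_stats> n=%d mean=%.4g median=%.4g mode=%.4g min=%.4g max=%.4g sd=%.4g skew=%.4g exkurt=%.4g\n",
    x$n, x$mean, x$median, x$mode, x$minimum, x$maximum, x$sd,
    x$skewness, x$kurtosis))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length `>= 3`, both with positive
#'   variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @examples
#' pearson_corr(1:4, c(2, 1, 4, 3))  # 0.6
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) {
    ldm_stop("ldm_stats_error", "length mismatch (%d vs %d)",
             length(x), length(y))
  }
  if (length(x) < 3L) {
    ldm_stop("ldm_stats_error", "need at least 3 paired observations")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    ldm_stop("ldm_correlation_undefined_error",
             "correlation undefined: zero variance")
  }
  stats::cor(x, y)
}

#' Assemble a machine-readable run report
#'
#' Aggregates every stage of a single-run analysis — metadata, speed-zone
#' summary, section splits, step table, symmetry reports and descriptive
#' statistics of the step variables — together with full processing
#' provenance (configurations, package version, artifact-mask summary,
#' seed if known), so a report re-read from disk reproduces the analysis
#' context.
#'
#' @param kin A `kinematic_series` (mandatory).
#' @param zones A `speed_zones` object, or `NULL`.
#' @param zone_summary Data frame from [zone_table()], or `NULL`.
#' @param splits A `section_splits` data frame, or `NULL`.
#' @param steps A `sprint_steps` data frame, or `NULL`.
#' @param symmetry A list of `symmetry_report` rows, or `NULL` (absent
#'   with a recorded warning when sides are unknown).
#' @param meta A [measurement_meta()], or `NULL`.
#' @param mask An `artifact_mask`, or `NULL`.
#' @param configs Named list of the configuration objects used.
#' @param seed Integer seed, if the run came from the simulator.
#' @return An object of class `run_report` (a nested list).
#' @export
build_report <- function(kin, zones = NULL, zone_summary = NULL,
                         splits = NULL, steps = NULL, symmetry = NULL,
                         meta = NULL, mask = NULL, configs = list(),
                         seed = NULL) {
  if (!inherits(kin, "kinematic_series")) {
    ldm_stop("ldm_report_error", "a kinematic_series is mandatory")
  }
  warnings <- character(0)
  if (is.null(symmetry) && !is.null(steps)) {
    warnings <- c(warnings,
                  "symmetry unavailable: step sides unknown or one-sided")
  }
  step_stats <- NULL
  if (!is.null(steps) && nrow(steps)) {
    vars <- c("support_s", "flight_s", "step_s", "length_m", "frequency_hz",
              "mean_speed")
    step_stats <- lapply(stats::setNames(vars, vars), function(v) {
      unclass(descriptive_stats(steps[[v]][!steps$boundary]))
    })
  }
  structure(list(
    meta = if (!is.null(meta)) unclass(meta) else NULL,
    run = list(
      n_samples = length(kin$t),
      duration_s = kin$t[length(kin$t)] - kin$t[1],
      peak_speed = if (!is.null(zones)) zones$v_max else max(kin$v_smooth),
      distance_m = max(kin$x)
    ),
    zones = zone_summary,
    splits = if (!is.null(splits)) as.data.frame(splits) else NULL,
    steps = if (!is.null(steps)) as.data.frame(steps) else NULL,
    symmetry = if (!is.null(symmetry)) {
      do.call(rbind, lapply(symmetry, as.data.frame))
    } else NULL,
    step_stats = step_stats,
    provenance = list(
      package = "sprintldm",
      version = as.character(utils::packageVersion("sprintldm")),
      configs = lapply(configs, unclass),
      seed = seed,
      artifact_segments = if (!is.null(mask)) as.data.frame(mask) else NULL,
      warnings = warnings
    )
  ), class = "run_report")
}

#' Write a run report as a JSON + CSV bundle
#'
#' Writes `report.json` plus flat CSVs (`splits.csv`, `steps.csv`,
#' `zones.csv`, `symmetry.json`, `mask.csv`) into a directory.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (!is.null(report$splits)) {
    utils::write.csv(report$splits, file.path(dir, "splits.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$steps)) {
    utils::write.csv(report$steps, file.path(dir, "steps.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$zones)) {
    utils::write.csv(report$zones, file.path(dir, "zones.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$symmetry)) {
    jsonlite::write_json(report$symmetry, file.path(dir, "symmetry.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(report$provenance$artifact_segments)) {
    utils::write.csv(report$provenance$artifact_segments,
                     file.path(dir, "mask.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read back a run report written by [write_report()]
#'
#' @param dir Directory containing `report.json`.
#' @return The parsed report (nested list).
#' @export
read_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}
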