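#' Measurement metadata
#'
#' Descriptive record of one measurement session: venue, conditions,
#' athlete anthropometry, start configuration, and the two parameters the
#' analysis itself consumes — the calibration distance `L1` and the maximum
#' speed tolerance used for speed-zone segmentation.
#'
#' @param calibration_distance_L1 Laser-to-start-line distance in meters
#'   (`> 0`).  Required for calibration.
#' @param max_speed_tolerance Fraction of peak speed defining the
#'   maximum-speed maintenance zone (default `0.02`, i.e. 2%); must lie in
#'   `(0, 0.5)`.
#' @param first_leg_on_start `"L"`, `"R"` or `"unknown"`: which leg takes the
#'   first step.  Needed for left/right side assignment and symmetry.
#' @param place,date,notes,sport_discipline Free-text descriptors.
#' @param wind Signed wind speed in m/s (positive = tailwind).
#' @param official_time,reaction_time Optional reference times in seconds.
#' @param measured_distance Race distance in meters (default 100).
#' @param athlete Named list (name, birth_date, country, height_cm,
#'   weight_kg, left_leg_cm, right_leg_cm); free-form, not interpreted.
#' @param dominant_hand,dominant_leg `"L"`, `"R"` or `NA`.
#' @param start_type `"moving"`, `"static-high"` or `"static-low"`.
#' @return An object of class `measurement_meta`.
#' @export
measurement_meta <- function(calibration_distance_L1,
                             max_speed_tolerance = 0.02,
                             first_leg_on_start = c("unknown", "L", "R"),
                             place = NA_character_, date = NA_character_,
                             wind = NA_real_, official_time = NA_real_,
                             reaction_time = NA_real_,
                             measured_distance = 100,
                             athlete = list(),
                             sport_discipline = NA_character_,
                             dominant_hand = NA_character_,
                             dominant_leg = NA_character_,
                             start_type = c("static-low", "static-high",
                                            "moving"),
                             notes = NA_character_) {
  check_scalar_number(calibration_distance_L1, "calibration_distance_L1",
                      lower = 1e-9, class = "ldm_calibration_error")
  check_scalar_number(max_speed_tolerance, "max_speed_tolerance",
                      lower = 1e-12, upper = 0.5 - 1e-12)
  first_leg_on_start <- match.arg(first_leg_on_start)
  start_type <- match.arg(start_type)
  structure(list(
    place = place, date = date, wind = wind, official_time = official_time,
    reaction_time = reaction_time, measured_distance = measured_distance,
    athlete = athlete, sport_discipline = sport_discipline,
    dominant_hand = dominant_hand, dominant_leg = dominant_leg,
    first_leg_on_start = first_leg_on_start, start_type = start_type,
    calibration_distance_L1 = calibration_distance_L1,
    max_speed_tolerance = max_speed_tolerance, notes = notes
  ), class = "measurement_meta")
}

#' @export
print.measurement_meta <- function(x, ...) {
  cat(sprintf(paste0(
    "<measurement_meta> L1 = %.3f m, max speed tolerance = %g,\n",
    "  first leg on start = %s, start = %s, distance = %g m\n"),
    x$calibration_distance_L1, x$max_speed_tolerance,
    x$first_leg_on_start, x$start_type, x$measured_distance))
  invisible(x)
}

# Flat key: value metadata files ---------------------------------------
#
# Metadata travels in a flat "key: value" text file (a strict subset of
# YAML): one scalar per line, '#' comments, athlete fields prefixed with
# "athlete_".  Kept deliberately flat so the files remain hand-editable
# and dependency-free.

#' Read measurement metadata from a flat key:value file
#'
#' @param path Path to a text file of `key: value` lines (athlete fields as
#'   `athlete_<field>`); `#` starts a comment.
#' @return A [measurement_meta()].
#' @export
read_meta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([A-Za-z0-9_]+)[[:space:]]*:[[:space:]]*(.*)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    ldm_stop("ldm_parse_error", "metadata line not 'key: value': '%s'",
             lines[bad][1])
  }
  keys <- vapply(m, `[`, character(1), 2L)
  vals <- vapply(m, `[`, character(1), 3L)
  kv <- stats::setNames(as.list(vals), keys)
  num <- function(k, default = NA_real_) {
    if (is.null(kv[[k]])) default else as.numeric(gsub(",", ".", kv[[k]]))
  }
  chr <- function(k, default = NA_character_) {
    if (is.null(kv[[k]])) default else kv[[k]]
  }
  ath_keys <- grep("^athlete_", keys, value = TRUE)
  athlete <- stats::setNames(lapply(ath_keys, function(k) kv[[k]]),
                             sub("^athlete_", "", ath_keys))
  measurement_meta(
    calibration_distance_L1 = num("calibration_distance_L1"),
    max_speed_tolerance = num("max_speed_tolerance", 0.02),
    first_leg_on_start = chr("first_leg_on_start", "unknown"),
    place = chr("place"), date = chr("date"), wind = num("wind"),
    official_time = num("official_time"), reaction_time = num("reaction_time"),
    measured_distance = num("measured_distance", 100),
    athlete = athlete, sport_discipline = chr("sport_discipline"),
    dominant_hand = chr("dominant_hand"), dominant_leg = chr("dominant_leg"),
    start_type = chr("start_type", "static-low"), notes = chr("notes")
  )
}

#' Write measurement metadata to a flat key:value file
#'
#' @param meta A [measurement_meta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meta <- function(meta, path) {
  stopifnot(inherits(meta, "measurement_meta"))
  flat <- meta[setdiff(names(meta), "athlete")]
  keep <- !vapply(flat, function(v) length(v) == 1L && is.na(v), logical(1))
  lines <- sprintf("%s: %s", names(flat)[keep],
                   vapply(flat[keep], function(v) format(v, digits = 15),
                          character(1)))
  if (length(meta$athlete)) {
    lines <- c(lines, sprintf("athlete_%s: %s", names(meta$athlete),
                              vapply(meta$athlete, as.character, character(1))))
  }
  writeLines(lines, path)
  invisible(path)
}
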