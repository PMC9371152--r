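#' Construct a raw laser distance-measurement trace
#'
#' A raw trace holds sampled time (seconds) and distance from the laser to
#' the tracked point on the athlete (meters), as captured by an LDM device
#' at a nominal 100 Hz.  Distances may contain `NA`/`NaN` where the beam
#' lost contact; those samples are handled downstream by
#' [detect_artifacts()] / [repair_artifacts()].
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param d Numeric vector of raw laser distances in meters, same length as
#'   `t`.  Non-finite values mark missing samples.
#' @param nominal_rate Nominal sampling rate in Hz.  If `NULL`, inferred as
#'   `1 / median(diff(t))` rounded to the nearest integer.
#' @return An object of class `ldm_trace`: a list with elements `t`, `d`
#'   and `nominal_rate`.
#' @seealso [parse_ldm_text()], [apply_calibration()]
#' @export
ldm_trace <- function(t, d, nominal_rate = NULL) {
  t <- as.double(t)
  d <- as.double(d)
  if (length(t) == 0L) {
    ldm_stop("ldm_parse_error", "trace is empty")
  }
  if (length(t) != length(d)) {
    ldm_stop("ldm_parse_error",
             "time and distance have different lengths (%d vs %d)",
             length(t), length(d))
  }
  if (anyNA(t) || any(!is.finite(t))) {
    ldm_stop("ldm_parse_error", "sample times must all be finite")
  }
  if (length(t) > 1L && any(diff(t) <= 0)) {
    ldm_stop("ldm_parse_error", "sample times must be strictly increasing")
  }
  med_dt <- if (length(t) > 1L) stats::median(diff(t)) else NA_real_
  if (is.null(nominal_rate)) {
    nominal_rate <- if (is.na(med_dt)) 100 else round(1 / med_dt)
  }
  check_scalar_number(nominal_rate, "nominal_rate", lower = 1e-9,
                      class = "ldm_parse_error")
  if (!is.na(med_dt) && abs(med_dt - 1 / nominal_rate) > 0.1 / nominal_rate) {
    ldm_stop("ldm_parse_error",
             "median sampling interval %.4g s deviates more than 10%% from 1/%g s",
             med_dt, nominal_rate)
  }
  structure(list(t = t, d = d, nominal_rate = as.double(nominal_rate)),
            class = "ldm_trace")
}

#' @export
print.ldm_trace <- function(x, ...) {
  n_miss <- sum(!is.finite(x$d))
  cat(sprintf(
    "<ldm_trace> %d samples @ %g Hz, t = [%.2f, %.2f] s, d = [%.2f, %.2f] m%s\n",
    length(x$t), x$nominal_rate, x$t[1], x$t[length(x$t)],
    suppressWarnings(min(x$d, na.rm = TRUE)),
    suppressWarnings(max(x$d, na.rm = TRUE)),
    if (n_miss) sprintf(" (%d missing)", n_miss) else ""))
  invisible(x)
}

#' Parse an LDM text trace
#'
#' The device writes plain-text files with time and distance either as two
#' long rows (first row time, second row distance) or transposed as two
#' columns.  Values may be separated by whitespace or semicolons and may use
#' either `.` or `,` as the decimal separator.
#'
#' @param text Character: the raw file content (a single string or a vector
#'   of lines).
#' @param dialect `"auto"` (default), `"row-wise"` or `"column-wise"`.
#'   `"auto"` resolves by shape: two long rows parse row-wise, many two-token
#'   lines parse column-wise.
#' @param units Units of the distance values: `"m"` (default) or `"mm"`
#'   (converted to meters by 1/1000; the device quotes its precision in mm).
#' @param nominal_rate Passed to [ldm_trace()]; `NULL` infers the rate.
#' @return An [ldm_trace()].
#' @examples
#' tr <- parse_ldm_text("0.00 0.01 0.02\n7.300 7.302 7.301")
#' tr$nominal_rate  # 100
#' @export
parse_ldm_text <- function(text, dialect = c("auto", "row-wise", "column-wise"),
                           units = c("m", "mm"), nominal_rate = NULL) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(gsub(";", " ", lines, fixed = TRUE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    ldm_stop("ldm_parse_error", "empty trace file")
  }
  toks <- strsplit(lines, "[[:space:]]+")
  num <- lapply(toks, function(v) {
    x <- suppressWarnings(as.numeric(gsub(",", ".", v, fixed = TRUE)))
    if (anyNA(x)) {
      bad <- v[is.na(x)]
      # literal NA/NaN tokens mark beam dropouts; anything else is a defect
      ok <- toupper(bad) %in% c("NA", "NAN")
      if (!all(ok)) {
        ldm_stop("ldm_parse_error", "non-numeric token '%s'", bad[!ok][1])
      }
    }
    x
  })
  if (dialect == "auto") {
    dialect <- if (length(num) == 2L) "row-wise" else "column-wise"
  }
  if (dialect == "row-wise") {
    if (length(num) != 2L) {
      ldm_stop("ldm_parse_error",
               "row-wise dialect expects 2 rows, found %d", length(num))
    }
    t <- num[[1]]
    d <- num[[2]]
  } else {
    nt <- lengths(num)
    if (any(nt != 2L)) {
      ldm_stop("ldm_parse_error",
               "column-wise dialect expects 2 values per line (line %d has %d)",
               which(nt != 2L)[1], nt[nt != 2L][1])
    }
    t <- vapply(num, `[`, numeric(1), 1L)
    d <- vapply(num, `[`, numeric(1), 2L)
  }
  if (length(t) != length(d)) {
    ldm_stop("ldm_parse_error",
             "time and distance counts differ (%d vs %d)", length(t), length(d))
  }
  if (units == "mm") d <- d / 1000
  ldm_trace(t, d, nominal_rate = nominal_rate)
}

#' Read an LDM trace from a file
#'
#' @param path Path to a plain-text LDM trace.
#' @inheritParams parse_ldm_text
#' @return An [ldm_trace()].
#' @export
read_ldm <- function(path, dialect = "auto", units = "m", nominal_rate = NULL) {
  parse_ldm_text(readLines(path, warn = FALSE), dialect = dialect,
                 units = units, nominal_rate = nominal_rate)
}

#' Serialize a trace back to the LDM text layout
#'
#' Inverse of [parse_ldm_text()]: writing and re-parsing reproduces `t` and
#' `d` bit-exactly (values are printed with `format(..., digits = 17)`).
#'
#' @param trace An [ldm_trace()] or calibrated trace (the raw `d` is written;
#'   for a calibrated trace, `x + L1`).
#' @param dialect `"row-wise"` or `"column-wise"`.
#' @param path Optional output file; if `NULL` the text is returned.
#' @return The text (invisibly when `path` is given).
#' @export
write_ldm_text <- function(trace, dialect = c("row-wise", "column-wise"),
                           path = NULL) {
  dialect <- match.arg(dialect)
  if (inherits(trace, "ldm_calibrated")) {
    d <- trace$x + trace$L1
  } else {
    d <- trace$d
  }
  ft <- format(trace$t, digits = 17, trim = TRUE, scientific = FALSE)
  fd <- vapply(d, function(v) {
    if (is.finite(v)) format(v, digits = 17, trim = TRUE, scientific = FALSE)
    else "NaN"
  }, character(1))
  text <- if (dialect == "row-wise") {
    paste(paste(ft, collapse = " "), paste(fd, collapse = " "), sep = "\n")
  } else {
    paste(paste(ft, fd), collapse = "\n")
  }
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}

#' Apply the start-line calibration
#'
#' Before a measurement the laser is aimed at a vertical bar standing on the
#' start line and the distance to it (the calibration distance `L1`) is
#' recorded.  Subtracting `L1` from every raw reading converts
#' distance-to-laser into displacement past the start line:
#' `x = d - L1` (the measuring distance is the difference between the actual
#' laser distance and the calibration distance).
#'
#' @param trace An [ldm_trace()].
#' @param L1 Calibration distance in meters, `> 0`.
#' @return An object of class `ldm_calibrated`: list with `t`, `x`, `L1`,
#'   `nominal_rate` and optionally `meta`.
#' @examples
#' tr <- ldm_trace(c(0, 0.01, 0.02), c(7.30, 7.31, 7.35))
#' apply_calibration(tr, 7.30)$x   # 0.00 0.01 0.05
#' @export
apply_calibration <- function(trace, L1) {
  stopifnot(inherits(trace, "ldm_trace"))
  if (!is.numeric(L1) || length(L1) != 1L || !is.finite(L1) || L1 <= 0) {
    ldm_stop("ldm_calibration_error",
             "calibration distance L1 must be a single positive number")
  }
  structure(list(t = trace$t, x = trace$d - L1, L1 = as.double(L1),
                 nominal_rate = trace$nominal_rate, meta = NULL),
            class = c("ldm_calibrated"))
}

#' @export
print.ldm_calibrated <- function(x, ...) {
  cat(sprintf(
    "<ldm_calibrated> %d samples @ %g Hz, L1 = %.3f m, x = [%.2f, %.2f] m\n",
    length(x$t), x$nominal_rate, x$L1,
    suppressWarnings(min(x$x, na.rm = TRUE)),
    suppressWarnings(max(x$x, na.rm = TRUE))))
  invisible(x)
}

#' Export a calibrated trace as a two-column CSV
#'
#' @param trace An `ldm_calibrated` trace.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ldm_calibrated"))
  utils::write.csv(data.frame(t = trace$t, x = trace$x), path,
                   row.names = FALSE)
  invisible(path)
}
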