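# Classed error conditions.  Every user-facing failure mode in the package
# signals a condition inheriting from "ldm_error" plus a specific subclass
# (e.g. "ldm_parse_error"), so callers and tests can discriminate with
# tryCatch()/expect_error(class = ...).

ldm_stop <- function(class, msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(structure(
    class = c(class, "ldm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ldm_warn <- function(class, msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  warning(structure(
    class = c(class, "ldm_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# shared argument checks ------------------------------------------------

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                class = "ldm_config_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    ldm_stop(class, "`%s` must be a single finite number in [%s, %s]",
             name, format(lower), format(upper))
  }
  invisible(x)
}
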