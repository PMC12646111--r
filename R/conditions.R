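# Structured error conditions. Every domain error carries a condition class of
# the form "resghg_<name>" so callers can test for specific failures with
# tryCatch()/expect_error(class = ...).

abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "resghg_error")))
}

warn <- function(message, class, ...) {
  warning(warningCondition(message, ..., class = c(class, "resghg_warning")))
}

stopifnot_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE", name), "resghg_bad_argument")
  }
  invisible(x)
}

stopifnot_number <- function(x, name, min = -Inf, max = Inf, finite = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (!finite || is.finite(x)) && x >= min && x <= max
  if (!ok) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
          "resghg_bad_argument")
  }
  invisible(x)
}
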