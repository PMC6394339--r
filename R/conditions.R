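# Structured error conditions used across the package.
# Classes: glv_validation_error (bad values/dimensions), glv_format_error
# (malformed files), glv_estimation_error, glv_simulation_error, glv_io_error.

glv_abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "glv_error")))
}

abort_validation <- function(msg, ...) glv_abort(msg, "glv_validation_error", ...)
abort_format     <- function(msg, ...) glv_abort(msg, "glv_format_error", ...)
abort_estimation <- function(msg, ...) glv_abort(msg, "glv_estimation_error", ...)
abort_simulation <- function(msg, ...) glv_abort(msg, "glv_simulation_error", ...)
abort_io         <- function(msg, ...) glv_abort(msg, "glv_io_error", ...)

# full-precision number formatting for TSV writers (17 significant digits,
# round-trips doubles)
format_full <- function(x) {
  sprintf("%.17g", x)
}
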