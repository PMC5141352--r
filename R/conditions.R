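# Structured error conditions so callers (and tests) can distinguish input
# validation failures from programming errors.

stop_validation <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg,
    class = c("gpcrscreen_validation_error", "gpcrscreen_error", "error")
  ))
}

stop_degenerate <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg,
    class = c("gpcrscreen_degenerate_error", "gpcrscreen_error", "error")
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
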