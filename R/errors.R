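#' @keywords internal
"_PACKAGE"

# Typed conditions: every user-facing failure carries a subclass of
# "modstick_error" so callers (and the test corpus) can distinguish
# format, parse and validation failures from plain R errors.

ms_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "modstick_error", "error"),
                      call = call))
}

ms_warn <- function(msg, class = "modstick_warning") {
  warning(warningCondition(msg, class = c(class, "modstick_warning")))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    ms_stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                    name, format(min), format(max)),
            "modstick_validation_error")
  invisible(x)
}
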