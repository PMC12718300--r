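# Classed conditions so callers and tests can distinguish failure modes:
#   airdisp_validation_error - malformed arguments (negative counts, bad names)
#   airdisp_shape_error      - mismatched grid dimensions
#   airdisp_domain_error     - mathematically undefined request (e.g. PWM with
#                              zero population, percent change from zero)
#   airdisp_io_error         - missing/unwritable files
#   airdisp_parse_error      - malformed file content (carries a line number)
stop_airdisp <- function(class, msg, call. = sys.call(-1)) {
  cond <- structure(
    class = c(class, "airdisp_error", "error", "condition"),
    list(message = msg, call = call.)
  )
  stop(cond)
}

stop_validation <- function(msg) stop_airdisp("airdisp_validation_error", msg, sys.call(-1))
stop_shape      <- function(msg) stop_airdisp("airdisp_shape_error", msg, sys.call(-1))
stop_domain     <- function(msg) stop_airdisp("airdisp_domain_error", msg, sys.call(-1))
stop_io         <- function(msg) stop_airdisp("airdisp_io_error", msg, sys.call(-1))
stop_parse      <- function(msg) stop_airdisp(c("airdisp_parse_error", "airdisp_io_error"), msg, sys.call(-1))

# scalar finite-number check used throughout
check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
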