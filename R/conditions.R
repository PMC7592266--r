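# Condition classes used across the package so that callers (and the CLI)
# can distinguish configuration mistakes, bad data, and usage errors.

abort_with <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "allquant_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @keywords internal
stop_config <- function(message) abort_with(message, "allquant_config_error")

#' @keywords internal
stop_data <- function(message) abort_with(message, "allquant_data_error")

#' @keywords internal
stop_domain <- function(message) abort_with(message, "allquant_domain_error")

#' @keywords internal
stop_usage <- function(message) abort_with(message, "allquant_usage_error")

#' @keywords internal
stop_validation <- function(message) abort_with(message, "allquant_validation_error")

# Round half away from zero, the display convention used throughout the
# reported tables (base round() is half-to-even and would turn 2.5 into 2).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
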