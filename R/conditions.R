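# Structured error conditions. Every error raised by the package carries the
# base class "mstmc_error" plus a subclass naming the failure category, so
# callers (and the CLI) can branch on error type instead of message text.

mstmc_abort <- function(message, class, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(class, "mstmc_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

abort_format    <- function(msg, ...) mstmc_abort(msg, "mstmc_error_format", ...)
abort_structure <- function(msg, ...) mstmc_abort(msg, "mstmc_error_structure", ...)
abort_lookup    <- function(msg, ...) mstmc_abort(msg, "mstmc_error_lookup", ...)
abort_binding   <- function(msg, ...) mstmc_abort(msg, "mstmc_error_binding", ...)
abort_order     <- function(msg, ...) mstmc_abort(msg, "mstmc_error_order", ...)
abort_range     <- function(msg, ...) mstmc_abort(msg, "mstmc_error_range", ...)
abort_syntax    <- function(msg, ...) mstmc_abort(msg, "mstmc_error_syntax", ...)
abort_horizon   <- function(msg, ...) mstmc_abort(msg, "mstmc_error_horizon", ...)
abort_numeric   <- function(msg, ...) mstmc_abort(msg, "mstmc_error_numeric", ...)
abort_config    <- function(msg, ...) mstmc_abort(msg, "mstmc_error_config", ...)
abort_registry  <- function(msg, ...) mstmc_abort(msg, "mstmc_error_registry", ...)
abort_parameter <- function(msg, ...) mstmc_abort(msg, "mstmc_error_parameter", ...)
abort_sample    <- function(msg, ...) mstmc_abort(msg, "mstmc_error_sample", ...)
abort_path      <- function(msg, ...) mstmc_abort(msg, "mstmc_error_path", ...)
abort_spec      <- function(msg, ...) mstmc_abort(msg, "mstmc_error_spec", ...)
abort_usage     <- function(msg, ...) mstmc_abort(msg, "mstmc_error_usage", ...)

# Signalled (not thrown) when a statistical function other than count() is
# applied to an empty collection; the enclosing comparison resolves to FALSE.
signal_empty_collection <- function(what) {
  cond <- structure(
    class = c("mstmc_empty_collection", "condition"),
    list(message = sprintf("empty collection under %s()", what), call = NULL)
  )
  stop(cond)
}
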