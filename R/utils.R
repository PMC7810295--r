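# Internal helpers: classed error conditions so callers can distinguish
# format, data, validation, design and domain failures programmatically.

rfa_abort <- function(message, class, ...) {
  cnd <- errorCondition(message, ..., class = c(class, "rfa_error"))
  stop(cnd)
}

abort_format <- function(message, ...) rfa_abort(message, "rfa_format_error", ...)
abort_data <- function(message, ...) rfa_abort(message, "rfa_data_error", ...)
abort_validation <- function(message, ...) rfa_abort(message, "rfa_validation_error", ...)
abort_design <- function(message, ...) rfa_abort(message, "rfa_design_error", ...)
abort_domain <- function(message, ...) rfa_abort(message, "rfa_domain_error", ...)
abort_spec <- function(message, ...) rfa_abort(message, "rfa_spec_error", ...)
abort_degenerate <- function(message, ...) rfa_abort(message, "rfa_degenerate_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Stable per-stream seed derivation: keep every derived seed a valid 32-bit
# integer whatever small integer the user supplies.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% .Machine$integer.max)
}
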