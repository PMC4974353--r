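# Classed conditions so callers (and the CLI) can distinguish bad files from
# bad values from bad configs.

nrf_error <- function(msg, class) {
  stop(structure(
    class = c(class, "nrf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

nrf_format_error <- function(msg) nrf_error(msg, "nrf_format_error")
nrf_value_error <- function(msg) nrf_error(msg, "nrf_value_error")
nrf_validation_error <- function(msg) nrf_error(msg, "nrf_validation_error")
nrf_design_error <- function(msg) nrf_error(msg, "nrf_design_error")
nrf_training_error <- function(msg) nrf_error(msg, "nrf_training_error")
nrf_io_error <- function(msg) nrf_error(msg, "nrf_io_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed-width significant-digit formatting shared by all table writers, so
# re-exporting identical objects is byte-identical.
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", sprintf("%.*g", digits, x))
}
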