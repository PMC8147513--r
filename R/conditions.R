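# Classed conditions so callers can distinguish failure modes programmatically.

dbs_error <- function(class, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "dbstune_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

#' @noRd
invalid_parameter <- function(message, ...) {
  dbs_error("dbstune_invalid_parameter", message, call = sys.call(-1), ...)
}

insufficient_data <- function(message, ...) {
  dbs_error("dbstune_insufficient_data", message, call = sys.call(-1), ...)
}

degenerate_design <- function(message, ...) {
  dbs_error("dbstune_degenerate_design", message, call = sys.call(-1), ...)
}

numerical_failure <- function(message, ...) {
  dbs_error("dbstune_numerical_failure", message, call = sys.call(-1), ...)
}

no_feasible_frequency <- function(message, ...) {
  dbs_error("dbstune_no_feasible_frequency", message, call = sys.call(-1), ...)
}

convergence_failure <- function(message, ...) {
  dbs_error("dbstune_convergence_failure", message, call = sys.call(-1), ...)
}

validation_error <- function(message, fields = character(), ...) {
  dbs_error("dbstune_validation_error", message, call = sys.call(-1),
            fields = fields, ...)
}

# An intolerable stimulation frequency is an *event*, not a programming error:
# the session loop catches it and lowers the tolerability ceiling.
intolerable_frequency <- function(frequency_hz) {
  dbs_error("dbstune_intolerable", sprintf(
    "stimulation at %g Hz was not tolerated", frequency_hz),
    call = sys.call(-1), frequency_hz = frequency_hz)
}
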