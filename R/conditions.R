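# Classed error conditions so callers and tests can distinguish failure modes.

stop_invalid_parameter <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("epimirnet_invalid_parameter", "error", "condition")))
}

stop_invalid_input <- function(msg) {
  stop(errorCondition(msg, class = c("epimirnet_invalid_input", "error", "condition")))
}

stop_degenerate_row <- function(msg) {
  stop(errorCondition(msg, class = c("epimirnet_degenerate_row", "error", "condition")))
}

stop_empty_model <- function(msg) {
  stop(errorCondition(msg, class = c("epimirnet_empty_model", "error", "condition")))
}

stop_configuration <- function(msg) {
  stop(errorCondition(msg, class = c("epimirnet_configuration_error", "error", "condition")))
}

stop_parse <- function(msg) {
  stop(errorCondition(msg, class = c("epimirnet_parse_error", "error", "condition")))
}
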