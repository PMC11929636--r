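# Structured error conditions so callers (and the CLI) can distinguish
# configuration mistakes, bad data, and optimizer failures.

config_error <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("supportnet_config_error", "supportnet_error")))
}

data_error <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("supportnet_data_error", "supportnet_error")))
}

convergence_error <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("supportnet_convergence_error", "supportnet_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
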