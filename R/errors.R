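# Classed conditions so callers (and the CLI) can distinguish bad input,
# bad configuration and statistical impossibilities.

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("coexhub_input_error", "coexhub_error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("coexhub_config_error", "coexhub_error")))
}

stop_stats <- function(...) {
  stop(errorCondition(paste0(...), class = c("coexhub_stats_error", "coexhub_error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("coexhub_io_error", "coexhub_error")))
}
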