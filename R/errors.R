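# Classed conditions so callers (and the CLI) can distinguish failure modes.
# Classes: gp_config_error, gp_format_error, gp_empty_input, gp_empty_result.

gp_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "gp_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

gp_config_error <- function(msg) gp_stop(msg, "gp_config_error")
gp_format_error <- function(msg) gp_stop(msg, "gp_format_error")
gp_empty_input  <- function(msg) gp_stop(msg, "gp_empty_input")
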