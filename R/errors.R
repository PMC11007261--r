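#' @keywords internal
"_PACKAGE"

# Classed condition helper so callers can distinguish validation failures
# (format/schema/range/alignment...) from ordinary errors.
ps_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "phylosym_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

ps_warn <- function(msg) warning(msg, call. = FALSE)
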