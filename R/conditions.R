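# Typed conditions. Every user-facing failure carries a subclass
# ("aortaz_<type>") so callers and the CLI can dispatch on it.

stop_typed <- function(subclass, message, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    class = c(paste0("aortaz_", subclass), "aortaz_error"),
    call = call
  ))
}

warn_typed <- function(subclass, message) {
  warning(warningCondition(
    message,
    class = c(paste0("aortaz_", subclass), "aortaz_warning")
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
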