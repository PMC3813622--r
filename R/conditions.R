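# Structured error conditions.  Every error raised by the package carries a
# subclass of "scanmut_error" so callers (and the batch drivers) can react to
# specific failure modes without parsing messages.

stop_scanmut <- function(class, message, ...) {
  cond <- structure(
    class = c(paste0("scanmut_", class), "scanmut_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
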