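# Classed conditions so callers (and tests) can distinguish failure modes.
# Every error raised by the package carries class c("fdtox_<kind>", "fdtox_error").

fd_stop <- function(kind, msg, ..., call. = FALSE) {
  stop(structure(
    class = c(paste0("fdtox_", kind), "fdtox_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

fd_assert <- function(ok, kind, msg, ...) {
  if (!isTRUE(ok)) fd_stop(kind, msg, ...)
  invisible(TRUE)
}
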