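# Classed conditions so callers can distinguish failure modes programmatically.
# Every engine error is a "voxann_error"; the first argument refines it, e.g.
# va_stop("schema", ...) signals class c("voxann_schema_error", "voxann_error").

va_stop <- function(type, ..., call. = FALSE) {
  msg <- paste0(...)
  cond <- structure(
    class = c(paste0("voxann_", type, "_error"), "voxann_error",
              "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

va_warn <- function(type, ...) {
  msg <- paste0(...)
  cond <- structure(
    class = c(paste0("voxann_", type, "_warning"), "voxann_warning",
              "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
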