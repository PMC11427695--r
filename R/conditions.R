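# Structured error conditions. The CLI maps condition classes to exit codes
# (usage 2, validation 3, io 4, internal 5); library users just see stop().

stop_usage <- function(msg, ...) {
  stop(condition_(msg, "mgidemux_usage_error", ...))
}

stop_validation <- function(msg, ...) {
  stop(condition_(msg, "mgidemux_validation_error", ...))
}

stop_io <- function(msg, ...) {
  stop(condition_(msg, "mgidemux_io_error", ...))
}

condition_ <- function(msg, class, call = sys.call(-1)) {
  structure(
    class = c(class, "mgidemux_error", "error", "condition"),
    list(message = msg, call = call)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
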