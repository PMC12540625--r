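# Classed conditions so callers can distinguish failure modes with
# tryCatch(..., spyquest_schema_too_small = ...) etc.

spy_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "spyquest_error"), call = call))
}

spy_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "spyquest_warning")))
}
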