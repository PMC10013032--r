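# Classed conditions so callers (and tests) can distinguish structural
# errors in net specifications from evaluation-time failures.

fop_structural_error <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("fop_structural_error", "fop_error")))
}

fop_evaluation_error <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("fop_evaluation_error", "fop_error")))
}

fop_schema_error <- function(msg, path = NULL) {
  stop(errorCondition(msg, path = path,
                      class = c("fop_schema_error", "fop_error")))
}

fop_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "fop_warning")))
}

# Per-event logging goes to stderr; gated by options(fopnet.verbose = TRUE).
fop_log <- function(...) {
  if (isTRUE(getOption("fopnet.verbose", FALSE))) {
    message(...)
  }
  invisible(NULL)
}
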