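# Shared error helpers. Every reader/constructor rejects malformed input
# with a classed condition so callers (and tests) can distinguish
# dimension, parse, schema and validation failures.

abort_dimension <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "fchybrid_error_dimension")
}

abort_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "fchybrid_error_validation")
}

abort_parse <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "fchybrid_error_parse")
}

abort_schema <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "fchybrid_error_schema")
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation("`%s` must be a single finite number", name)
  }
  invisible(x)
}
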