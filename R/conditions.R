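# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish domain errors (bad values, exit 1) from usage errors
# (bad invocation, exit 2).

stop_domain <- function(message, field = NULL, class = character()) {
  stop(structure(
    class = c(class, "diagbias_domain_error", "error", "condition"),
    list(message = message, call = sys.call(-1), field = field)
  ))
}

stop_usage <- function(message) {
  stop(structure(
    class = c("diagbias_usage_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stop_io <- function(message) {
  stop(structure(
    class = c("diagbias_io_error", "diagbias_domain_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# scalar probability check; errors name the offending field
check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_domain(
      sprintf("`%s` must be a single probability in [0, 1], got %s",
              field, paste(format(x), collapse = ", ")),
      field = field
    )
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
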