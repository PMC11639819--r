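# Classed conditions used across the package. Every error carries the
# "pedibca_error" class plus a specific subclass so callers (and the CLI
# dispatcher, which maps classes to exit codes) can react programmatically.

pbc_stop <- function(message, class, ...) {
  stop(errorCondition(message,
    ...,
    class = c(class, "pedibca_error", "error")
  ))
}

pbc_domain_error <- function(message, ...) {
  pbc_stop(message, class = c("pedibca_domain_error"), ...)
}

pbc_contract_error <- function(message, ...) {
  pbc_stop(message, class = c("pedibca_contract_error"), ...)
}

pbc_schema_error <- function(message, ...) {
  pbc_stop(message, class = c("pedibca_schema_error"), ...)
}

pbc_warn <- function(message, class = "pedibca_soft_warning") {
  warning(warningCondition(message, class = c(class, "pedibca_warning")))
}

# Scalar/vector numeric validation: finite, optionally bounded.
pbc_check_numeric <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) == 0L) {
    pbc_domain_error(sprintf("'%s' must be numeric and non-empty", name))
  }
  if (any(!is.finite(x))) {
    pbc_domain_error(sprintf("'%s' must be finite", name))
  }
  if (positive && any(x <= 0)) {
    pbc_domain_error(sprintf("'%s' must be strictly positive", name))
  }
  if (nonnegative && any(x < 0)) {
    pbc_domain_error(sprintf("'%s' must be non-negative", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
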