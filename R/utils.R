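stopf <- function(fmt, ..., class = "refsimba_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stopf("non-finite values in %s", what, class = "refsimba_invalid_parameter")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
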