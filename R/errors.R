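# Classed conditions so callers can distinguish failure modes programmatically.
# All error classes are prefixed "neckssm_error_" and inherit from
# "neckssm_error".

ssm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("neckssm_error_", class), "neckssm_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

ssm_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(paste0("neckssm_warning_", class), "neckssm_warning",
              "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x)))
    ssm_stop("nonfinite_input", "%s contains non-finite values", what)
  invisible(x)
}
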