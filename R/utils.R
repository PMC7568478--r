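## shared input-validation helpers

qh_validation_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("quantherit_validation_error",
                                             "error", "condition")))
}

qh_numeric_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("quantherit_numeric_error",
                                             "error", "condition")))
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    qh_validation_error(name, " must be a single number in [", lo, ", ", hi, "]")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    qh_validation_error(name, " must be an integer >= ", min)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
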