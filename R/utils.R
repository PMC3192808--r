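# Internal validation helpers shared across modules.

stopf <- function(fmt, ..., call. = FALSE) {
  stop(sprintf(fmt, ...), call. = call.)
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stopf("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stopf("'%s' must be an integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

# Standard one-letter amino-acid alphabet (20 residues).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
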