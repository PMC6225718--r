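# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# strict ">" on a ratio, robust to binary-float artifacts at the boundary
# (19/20 must NOT clear 0.95)
strictly_over <- function(num, den, frac) {
  num / den > frac + 1e-9
}

#' Reverse-complement DNA sequences
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be in [0, 1]", name), call. = FALSE)
  invisible(x)
}
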