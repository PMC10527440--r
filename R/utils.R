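# Classed error conditions used across the package. Exit-code mapping for
# the command-line wrapper: validation -> 2, io -> 3, degenerate -> 4.

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cchp_validation_error", "cchp_error")))
}

abort_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cchp_io_error", "cchp_error")))
}

abort_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cchp_degenerate_error", "cchp_error")))
}

assert_numeric_vector <- function(x, min_len, what) {
  if (!is.numeric(x) || length(x) < min_len)
    abort_validation("%s must be a numeric vector of length >= %d", what, min_len)
  if (anyNA(x) || any(!is.finite(x)))
    abort_validation("%s contains non-finite values", what)
  invisible(x)
}

# Deterministic child seed derivation; keeps results inside 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 + 7919 * as.double(index)) %% 2147483647)
}

# Run an expression with a private RNG state so callers' streams are intact.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
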