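# Internal helpers: validation and seed management.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_field(field, sprintf(
      "value %g outside %s%g, %g%s", x,
      if (open_lower) "(" else "[", lower, upper,
      if (open_upper) ")" else "]"))
  }
  x
}

#' Evaluate code with a temporary, restorable RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a call is a pure function of its arguments and seed:
#' the global RNG stream of the caller is left untouched.
#'
#' @param seed integer seed.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Derive a deterministic sub-seed for operation `k` from a base seed, kept
# within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}
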