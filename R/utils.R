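`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so callers (and tests) can distinguish failure modes.
abort_clampresp <- function(message, class) {
  stop(errorCondition(message, class = c(class, "clampresp_error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Trapezoidal integral
#'
#' @param x ordered abscissa values.
#' @param y ordinates.
#' @return the trapezoid-rule integral of `y` over `x`.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n])) / 2
}

# Deterministic per-unit seed derivation; stays below 2^31 - 1.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 10007 * as.numeric(i)) %% 2147483646 + 1)
}

# Evaluate code under a seed when one is given, without touching the
# global RNG stream otherwise.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Longest run of TRUE in a logical vector.
max_true_run <- function(flags) {
  if (!length(flags) || !any(flags)) return(0L)
  r <- rle(as.logical(flags))
  max(r$lengths[r$values])
}
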