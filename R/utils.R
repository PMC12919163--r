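#' @useDynLib flashvep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Half-up (away from zero) rounding; base round() rounds half to even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Event times are stored in seconds; sample indices are derived by rounding
# half-up wherever a time meets the sample grid (0-based index).
time_to_sample <- function(t, fs) as.integer(floor(t * fs + 0.5))

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr with the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic stream splitting: derive a child seed for sub-task k so that
# schedule, noise, split and training draws never share a stream. Arithmetic
# stays below 2^53 so the double computation is exact; result is in [1, 2^31).
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 1664525 + as.double(k) * 1013904223
  as.integer(s %% 2147483563) + 1L
}

assert_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < lower)
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  invisible(x)
}
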