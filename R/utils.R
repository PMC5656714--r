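## internal helpers: validation, seeded evaluation, child-seed derivation

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, min = -Inf, max = Inf,
                              strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_min && x <= min) stopf("`%s` must be > %g (got %g)", name, min, x)
  if (!strict_min && x < min) stopf("`%s` must be >= %g (got %g)", name, min, x)
  if (x > max) stopf("`%s` must be <= %g (got %g)", name, max, x)
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded simulation internals never disturb a
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed from a base seed and a counter
#'
#' Counter-based scheme used by the experiment runner and the calibration
#' loop: each (scenario, replicate) pair gets an independent, individually
#' re-simulatable seed. Two multiplicative-congruential steps (MINSTD
#' multiplier 48271 modulo 2^31 - 1) mix the counter into the base seed; all
#' arithmetic stays below 2^53 so it is exact in doubles, and the result is
#' always a positive integer below 2^31.
#'
#' @param base_seed integer base seed.
#' @param counter non-negative integer replicate counter.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1L, 0:3)
child_seed <- function(base_seed, counter) {
  assert_scalar_num(base_seed, "base_seed")
  m <- 2147483647
  s <- (abs(base_seed) %% m)
  out <- vapply(counter, function(k) {
    x <- (s * 48271 + k + 1) %% m
    x <- (x * 48271 + k + 1) %% m
    if (x == 0) x <- 1
    x
  }, numeric(1))
  as.integer(out)
}

## Gaussian smoothing with periodic boundaries, applied in the frequency
## domain: multiply the 2-D FFT by the Gaussian transfer function
## exp(-2 pi^2 sigma^2 |f|^2). Exact for any sigma and any image size
## (no kernel-truncation limit), and deterministic.
gaussian_smooth_periodic <- function(z, sigma) {
  if (sigma <= 0) return(z)
  rows <- nrow(z); cols <- ncol(z)
  fr <- (seq_len(rows) - 1) / rows
  fr <- pmin(fr, 1 - fr)  # wrap to [-0.5, 0.5]
  fc <- (seq_len(cols) - 1) / cols
  fc <- pmin(fc, 1 - fc)
  transfer <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, `+`))
  Re(stats::fft(stats::fft(z) * transfer, inverse = TRUE)) / (rows * cols)
}

## smoothed, unit-variance correlated noise field; sd-normalised so
## texture_amplitude is the field's relative standard deviation regardless
## of the correlation length
correlated_noise <- function(rows, cols, corr_length) {
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  if (corr_length > 0) {
    z <- gaussian_smooth_periodic(z, corr_length)
    s <- stats::sd(z)
    if (s > 0) z <- z / s
  }
  z
}
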