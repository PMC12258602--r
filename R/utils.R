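#' Derive a reproducible sub-seed from a root seed
#'
#' All stochastic components of the package draw their randomness from one
#' root integer seed; sub-streams (per rater, per simulation corner, per
#' pipeline stage) use seeds derived deterministically from it so that runs
#' are reproducible while sub-streams stay decorrelated.
#'
#' @param seed root integer seed.
#' @param index non-negative integer identifying the sub-stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(index), length(index) == 1, index >= 0)
  # multiplicative hash mod a Mersenne prime keeps the result a valid R seed
  as.integer((((abs(seed) %% 2147483647) * 48271) + index) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Linear interpolation of a sampled function u(y) onto a new y grid.
interp_at <- function(y, u, y_out) {
  stats::approx(y, u, xout = y_out, rule = 2)$y
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# type-7 quantiles, as stats::quantile default; named for intent at call sites
iqr_of <- function(x) unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25))
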