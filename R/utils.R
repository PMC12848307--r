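# Internal helpers shared across modules.

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations take an
# explicit seed and go through this; there is no hidden global state.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Centred moving average with window of `k` samples (k odd recommended);
# shrinks the window at the edges rather than dropping samples.
rollMean <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n == 0) return(x)
  half <- floor(k / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Linear detrend of y against x; returns residuals.
detrendLinear <- function(x, y) {
  stats::residuals(stats::lm(y ~ x))
}

stopIfNotPositive <- function(..., msg) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals <= 0)) stop(msg, call. = FALSE)
}
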