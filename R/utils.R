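# Internal numerical helpers shared across modules.

# Evaluate a polynomial given coefficients in INCREASING order of power.
polyval_inc <- function(coef, x) {
  drop(outer(x, seq_along(coef) - 1L, `^`) %*% coef)
}

# Linear interpolation of the position where a piecewise-linear curve crosses
# `level`, searching between indices i and i+1. Returns NA if no crossing.
cross_between <- function(x, y, level, i) {
  y0 <- y[i]
  y1 <- y[i + 1L]
  if ((y0 - level) * (y1 - level) > 0) {
    return(NA_real_)
  }
  if (y1 == y0) {
    return(x[i])
  }
  x[i] + (level - y0) * (x[i + 1L] - x[i]) / (y1 - y0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
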