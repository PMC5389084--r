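`%||%` <- function(a, b) if (is.null(a)) b else a

# Literal triple-sum estimator of the squared distance covariance: evaluates
# the double and triple sums term by term, with no vectorisation shortcuts.
# Deliberately naive; the reference the fast kernel is checked against.
bruteDcov2 <- function(x, y) {
  n <- length(x)
  s1 <- 0; s2a <- 0; s2b <- 0; s3 <- 0
  for (i1 in seq_len(n)) {
    for (i2 in seq_len(n)) {
      s1 <- s1 + abs(y[i1] - y[i2]) * abs(x[i1] - x[i2])
      s2a <- s2a + abs(y[i1] - y[i2])
      s2b <- s2b + abs(x[i1] - x[i2])
    }
  }
  for (i1 in seq_len(n)) {
    for (i2 in seq_len(n)) {
      for (i3 in seq_len(n)) {
        s3 <- s3 + abs(y[i1] - y[i3]) * abs(x[i2] - x[i3])
      }
    }
  }
  s1 / n^2 + (s2a / n^2) * (s2b / n^2) - 2 * s3 / n^3
}

bruteDcorr <- function(x, y) {
  vxy <- bruteDcov2(x, y)
  vxx <- bruteDcov2(x, x)
  vyy <- bruteDcov2(y, y)
  if (vxx <= 0 || vyy <= 0) return(0)
  sqrt(vxy / sqrt(vxx * vyy))
}

# Univariate SCAD objective minimised by dense grid search: for an orthonormal
# design the penalised problem separates into these per-coordinate problems.
gridScadArgmin <- function(z, lambda, alpha, step = 1e-5) {
  grid <- seq(-abs(z) - 1, abs(z) + 1, by = step)
  obj <- 0.5 * (grid - z)^2 +
    vapply(abs(grid), scadPenalty, numeric(1), lambda = lambda, alpha = alpha)
  grid[which.min(obj)]
}

# Greedy one-at-a-time iterative screen written independently of the package
# internals: at each step pick the remaining feature whose least-squares
# residual (on the selected set plus intercept) has the largest brute-force
# distance correlation with y.
greedyIterativeOrder <- function(x, y) {
  p <- ncol(x)
  selected <- integer(0)
  remaining <- seq_len(p)
  while (length(remaining)) {
    sc <- vapply(remaining, function(j) {
      v <- if (length(selected)) {
        stats::resid(stats::lm(x[, j] ~ x[, selected, drop = FALSE]))
      } else x[, j]
      bruteDcorr(v, y)
    }, numeric(1))
    pick <- remaining[which.max(sc)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}
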