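# Independent oracles, written as literal step-by-step transcriptions of the
# defining formulas. They deliberately avoid the package's code paths (and
# vectorized shortcuts) so they can serve as cross-checks.

oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Literal biweight midcorrelation: median, unscaled MAD, tuning constant 9,
# Tukey biweights, weighted median-centered vectors normalized to unit length.
oracle_bicor <- function(x, y) {
  standardize <- function(v) {
    med <- oracle_median(v)
    mad0 <- oracle_median(abs(v - med))
    z <- numeric(length(v))
    if (mad0 > 0) {
      for (i in seq_along(v)) {
        u <- (v[i] - med) / (9 * mad0)
        w <- if (abs(u) < 1) (1 - u^2)^2 else 0
        z[i] <- (v[i] - med) * w
      }
    } else {
      for (i in seq_along(v)) z[i] <- v[i] - sum(v) / length(v)
    }
    norm2 <- 0
    for (i in seq_along(z)) norm2 <- norm2 + z[i]^2
    z / sqrt(norm2)
  }
  zx <- standardize(x)
  zy <- standardize(y)
  out <- 0
  for (i in seq_along(zx)) out <- out + zx[i] * zy[i]
  out
}

# Two-sided correlation p-value by numerical integration of the Student-t
# density (no calls to pt).
oracle_t_pvalue <- function(r, n) {
  df <- n - 2
  tval <- abs(r) * sqrt(df) / sqrt(1 - r^2)
  dens <- function(t) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + t^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, tval, Inf, rel.tol = 1e-10)$value
}

# Closed-form simple least squares: slope and intercept of y ~ x.
oracle_ols <- function(x, y) {
  xbar <- mean(x)
  ybar <- mean(y)
  slope <- sum((x - xbar) * (y - ybar)) / sum((x - xbar)^2)
  c(intercept = ybar - slope * xbar, slope = slope)
}
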