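# Independent brute-force oracles, kept free of the package's code paths.

# OLS by the normal equations, written out longhand.
ols_oracle <- function(x, y) {
  xbar <- sum(x) / length(x)
  ybar <- sum(y) / length(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  list(slope = slope, intercept = ybar - slope * xbar)
}

# One-way balanced ANOVA mean squares from the defining sums of squares.
anova_oracle <- function(series, values) {
  groups <- split(values, series)
  p <- length(groups)
  n <- length(groups[[1]])
  grand <- mean(values)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  ssb <- n * sum(vapply(groups, function(g) (mean(g) - grand)^2, numeric(1)))
  list(ms_within = ssw / (p * (n - 1)), ms_between = ssb / (p - 1),
       grand_mean = grand, p = p, n = n)
}

# Paired t from the textbook formula.
paired_t_oracle <- function(x, y) {
  d <- x - y
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * pt(-abs(tstat), df = n - 1))
}

# Relative beta-ETI bounds published for the captopril assay (seven levels,
# lambda = 10%), with the trueness-row biases.
published_intervals <- function() {
  tibble::tibble(
    level_pct = c(5, 10, 25, 50, 75, 100, 120),
    bias_pct = c(-2.3, 3.3, 1.0, 2.3, 3.5, 0.3, 1.6),
    eti_low_pct = c(-9.00, -1.77, -5.42, -1.81, -1.60, -5.59, -2.62),
    eti_high_pct = c(4.33, 8.29, 7.34, 6.47, 5.41, 6.09, 5.74)
  )
}

# Expected content of a relative-scale tolerance interval under the
# generating model: future results are Normal(bias, sqrt(sB^2 + sW^2)) on
# the same relative scale (small-noise regime where relative Gaussian
# errors stay Gaussian).
interval_content <- function(low, high, bias, s_total) {
  pnorm((high - bias) / s_total) - pnorm((low - bias) / s_total)
}
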