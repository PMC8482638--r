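# Independent oracles, kept deliberately naive.

# Classical chi-square dispersion statistic via an explicit per-element
# loop (no vectorisation shared with the implementation).
classical_chi2_loop <- function(x) {
  m <- sum(x) / length(x)
  s <- 0
  for (xi in x) s <- s + (xi - m)^2 / m
  s
}

# Chi-square quantile by bisection on the regularized lower incomplete
# gamma function P(df/2, x/2) (the chi-square CDF), independent of qchisq.
chisq_quantile_bisect <- function(p, df, tol = 1e-12) {
  cdf <- function(x) pgamma(x / 2, shape = df / 2)  # regularized P(a, x)
  lo <- 0
  hi <- max(df * 10, 100)
  while (cdf(hi) < p) hi <- hi * 2
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Random interval-count dataset for property loops.
random_interval_data <- function(k = 20, lo_range = c(5, 80),
                                 max_width = 30) {
  lo <- sample(seq(lo_range[1], lo_range[2]), k, replace = TRUE)
  interval_counts(lo, lo + sample(0:max_width, k, replace = TRUE))
}
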