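test_that("neutrosophic mean averages each component", {
  m <- neutrosophic_mean(pulse_counts())
  expect_equal(m$l_value, 73.54)
  expect_equal(m$u_value, 91.8)

  expect_equal(as.numeric(neutrosophic_mean(interval_counts(44, 68))),
               c(44, 68))
  expect_equal(as.numeric(neutrosophic_mean(interval_counts(c(1, 3), c(2, 4)))),
               c(2, 3))
})

test_that("equal-time statistic matches hand oracles and published values", {
  s <- chi2_equal_time(pulse_counts())
  expect_equal(round(s$l_value, 4), 146.9733)
  expect_equal(round(s$u_value, 4), 121.7865)

  terms <- chi2_terms(pulse_counts())
  expect_equal(round(terms$lower[1], 2), 11.87)
  expect_equal(round(terms$upper[1], 2), 6.17)

  # all deviations vanish on identical intervals
  same <- interval_counts(rep(10, 5), rep(20, 5))
  expect_equal(as.numeric(chi2_equal_time(same)), c(0, 0))

  # crisp {4, 6}: mean 5, (1 + 1)/5 per component; equals the classical test
  crisp <- interval_counts(c(4, 6))
  expect_equal(as.numeric(chi2_equal_time(crisp)), c(0.4, 0.4))
  expect_equal(chi2_equal_time(crisp)$l_value, classical_chi2_loop(c(4, 6)))

  expect_error(chi2_equal_time(interval_counts(5, 7)), "at least 2")
  expect_error(chi2_equal_time(interval_counts(c(0, 0), c(1, 2))),
               "degenerate data")
})

test_that("unequal-time statistic uses the pooled rate per component", {
  # rate 30/3 = 10; expected 10 and 20 match observed exactly
  z <- chi2_unequal_time(interval_counts(c(10, 20)), c(1, 2))
  expect_equal(as.numeric(z), c(0, 0))

  # expected 10, 20; (2^2)/10 + (2^2)/20 = 0.6
  s <- chi2_unequal_time(interval_counts(c(12, 18)), c(1, 2))
  expect_equal(as.numeric(s), c(0.6, 0.6))

  r <- neutrosophic_rate(interval_counts(c(10, 20), c(14, 22)), c(1, 2))
  expect_equal(r$l_value, 10)
  expect_equal(r$u_value, 12)

  expect_error(chi2_unequal_time(interval_counts(c(1, 2)), c(1, 0)),
               "nonpositive observation time")
  expect_error(chi2_unequal_time(interval_counts(c(1, 2)), 1),
               "one period per count")
  expect_error(chi2_unequal_time(interval_counts(c(0, 0)), c(1, 2)),
               "total count is zero")
})

test_that("constant observation times reduce to the equal-time statistic", {
  set.seed(11)
  for (i in 1:100) {
    x <- random_interval_data(k = sample(3:40, 1))
    tt <- rep(runif(1, 0.5, 5), nrow(x))
    a <- chi2_unequal_time(x, tt)
    b <- chi2_equal_time(x)
    expect_equal(a$l_value, b$l_value, tolerance = 1e-9)
    expect_equal(a$u_value, b$u_value, tolerance = 1e-9)
  }
})

test_that("crisp data recover the classical statistic computed by a naive loop", {
  set.seed(12)
  for (i in 1:50) {
    v <- sample(5:120, sample(3:30, 1), replace = TRUE)
    s <- chi2_equal_time(interval_counts(v))
    expect_equal(s$l_value, classical_chi2_loop(v), tolerance = 1e-9)
    expect_equal(s$u_value, s$l_value)
    expect_equal(neutro_form(s)$i_upper, 0)
  }
})

test_that("production summation agrees with a per-element reference loop on intervals", {
  set.seed(13)
  for (i in 1:50) {
    x <- random_interval_data(k = sample(3:30, 1))
    s <- chi2_equal_time(x)
    expect_equal(s$l_value, classical_chi2_loop(x$lower), tolerance = 1e-9)
    expect_equal(s$u_value, classical_chi2_loop(x$upper), tolerance = 1e-9)
    expect_gte(s$l_value, 0)
    expect_gte(s$u_value, 0)
  }
})

test_that("critical region matches chi-square quantiles and validates alpha", {
  cr <- critical_region(0.05, 50)
  expect_equal(round(unname(cr), 2), c(34.76, 67.50))
  expect_lt(cr[["lower"]], cr[["upper"]])

  cr1 <- critical_region(0.05, 50, df_rule = "K-1")
  expect_equal(unname(cr1), qchisq(c(0.05, 0.95), 49), tolerance = 1e-12)

  expect_error(critical_region(0, 50), "between 0 and 0.5")
  expect_error(critical_region(0.5, 50), "between 0 and 0.5")
  expect_error(critical_region(0.05, 1), ">= 2")

  # near alpha = 0.5 both critical values close on the median
  cr49 <- critical_region(0.499, 10)
  expect_lt(cr49[["upper"]] - cr49[["lower"]], 0.05)
})

test_that("critical values agree with a bisection oracle on the incomplete gamma", {
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    for (df in c(2, 5, 10, 50, 120)) {
      cr <- critical_region(alpha, df)
      expect_equal(cr[["lower"]], chisq_quantile_bisect(alpha, df),
                   tolerance = 1e-6)
      expect_equal(cr[["upper"]], chisq_quantile_bisect(1 - alpha, df),
                   tolerance = 1e-6)
    }
  }
})

test_that("decision is tri-state, exhaustive, and symmetric in the pair", {
  expect_equal(decide(neutro_pair(146.97, 121.78), 34.76, 67.50), "reject")
  expect_equal(decide(neutro_pair(40, 50), 34.76, 67.50), "not_reject")
  expect_equal(decide(neutro_pair(40, 120), 34.76, 67.50), "indeterminate")
  # a component exactly on a critical value counts as inside
  expect_equal(decide(neutro_pair(34.76, 67.50), 34.76, 67.50), "not_reject")
  expect_error(decide(neutro_pair(1, 2), 5, 5), "less than")

  set.seed(14)
  for (i in 1:100) {
    s <- neutro_pair(runif(1, 0, 100), runif(1, 0, 100))
    d <- decide(s, 34.76, 67.50)
    expect_true(d %in% c("reject", "not_reject", "indeterminate"))
    expect_identical(decide(neutro_pair(s$u_value, s$l_value), 34.76, 67.50), d)
  }
})

test_that("the composed test reproduces the worked example and edge outcomes", {
  res <- nchisq_test(pulse_counts(), alpha = 0.05)
  expect_s3_class(res, "nchisq_test")
  expect_equal(res$decision, "reject")
  expect_equal(res$df, 50L)
  expect_equal(res$form$base, res$statistic$l_value)
  expect_equal(round(res$form$i_upper, 4), 0.2068)
  expect_equal(sum(res$terms$lower), res$statistic$l_value, tolerance = 1e-12)
  expect_equal(sum(res$terms$upper), res$statistic$u_value, tolerance = 1e-12)

  flat <- nchisq_test(interval_counts(rep(70, 10)))
  expect_equal(as.numeric(flat$statistic), c(0, 0))
  expect_equal(flat$decision, "reject")  # 0 is below the lower critical value

  res2 <- nchisq_test(straddling_data(), alpha = 0.05)
  expect_equal(res2$decision, "indeterminate")

  timed <- nchisq_test(interval_counts(c(40, 50), c(41, 52)), times = c(1, 1))
  expect_match(timed$method, "unequal-time")
})
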