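test_that("lnq construction enforces the multiplicative-error invariants", {
  x <- lnq(100, 2)
  expect_equal(lnq_shape(x), log(2))
  expect_equal(ci95(x), c(100 * 2^-1.96, 100 * 2^1.96))
  expect_equal(ci95(x)[1], 25.7, tolerance = 1e-3)
  expect_equal(ci95(x)[2], 389.0, tolerance = 1e-3)

  expect_lnq_equal(lnq(5, 1), 5, 1)   # exact value, s = 0
  expect_equal(lnq_shape(lnq(1000, 1.3)), 0.2624, tolerance = 1e-3)

  expect_error(lnq(0, 2), "positive")
  expect_error(lnq(-3, 2), "positive")
  expect_error(lnq(10, 0.9), ">= 1")
  expect_error(lnq(c(1, 2), 2), "single")
})

test_that("from_interval symmetrizes a 95% CI on the log scale", {
  expect_equal(from_interval(100, 25.7, 389)$factor, 2, tolerance = 1e-3)
  expect_lnq_equal(from_interval(100, 100, 100), 100, 1)
  x <- from_interval(141, 50, 400)
  expect_equal(lnq_shape(x), log(8) / 3.92, tolerance = 1e-10)
  expect_equal(x$factor, 1.70, tolerance = 1e-2)
  expect_error(from_interval(100, 120, 150), "ci_low <= median")
  expect_error(from_interval(100, 0, 150), "ci_low")
})

test_that("ci95 and from_interval are mutual inverses on the factor", {
  for (f in c(1, 1.1, 1.5, 2, 3.7)) {
    x <- lnq(42, f)
    ci <- ci95(x)
    expect_equal(from_interval(x$median, ci[1], ci[2])$factor, f)
  }
})

test_that("products and ratios follow the root-sum-square shape rule", {
  p <- lnq_mul(lnq(3, 2), lnq(4, 2))
  expect_lnq_equal(p, 12, 2^sqrt(2), tol = 1e-12)
  expect_equal(p$factor, 2.665, tolerance = 1e-3)

  # commutativity and exact-scalar neutrality
  x <- lnq(7, 1.8)
  expect_equal(lnq_mul(x, lnq(2, 1.3)), lnq_mul(lnq(2, 1.3), x))
  expect_lnq_equal(lnq_mul(x, lnq(5, 1)), 35, 1.8)

  q <- lnq_div(lnq(1500, 1.5), lnq(3.9e6, 2))
  expect_equal(q$median, 3.846e-4, tolerance = 1e-3)
  expect_equal(q$factor, exp(sqrt(log(1.5)^2 + log(2)^2)), tolerance = 1e-12)
  expect_equal(q$factor, 2.232, tolerance = 1e-3)

  # operands treated as independent: x / x keeps spread
  r <- lnq_div(x, x)
  expect_equal(r$median, 1)
  expect_gt(r$factor, x$factor)
  expect_equal(lnq_div(x, lnq(1, 1)), x)

  # Ops sugar
  expect_equal(lnq(3, 2) * lnq(4, 2), p)
  expect_equal(lnq(1500, 1.5) / lnq(3.9e6, 2), q)
  expect_error(lnq(1, 2) + lnq(1, 2), "not defined")
})

test_that("product factor dominates the larger operand factor", {
  set.seed(11)
  for (i in 1:20) {
    fx <- exp(abs(rnorm(1, 0, 0.5)))
    fy <- exp(abs(rnorm(1, 0, 0.5)))
    f <- lnq_mul(lnq(1, fx), lnq(1, fy))$factor
    expect_gte(f, max(fx, fy))
  }
})

test_that("fit_lognormal uses log-scale mean and population SD", {
  expect_lnq_equal(fit_lognormal(rep(3.5, 10)), 3.5, 1)
  expect_lnq_equal(fit_lognormal(c(1, exp(2))), exp(1), exp(1))
  expect_error(fit_lognormal(c(1, -1, 2)), "positive")
  expect_error(fit_lognormal(5), "two samples")
})

test_that("fit_lognormal inverts lnq sampling (self-consistency)", {
  x <- lnq(100, 2)
  fit <- withr::with_seed(7, fit_lognormal(lnq_sample(x, 1e6)))
  expect_equal(fit$median, 100, tolerance = 0.01)
  expect_equal(fit$factor, 2, tolerance = 0.01)
})

test_that("bootstrap_sum handles degenerate and single-element sums", {
  one <- bootstrap_sum(list(lnq(100, 1.5)), n_samples = 1e5, seed = 3)
  expect_equal(one$median, 100, tolerance = 0.02)
  expect_equal(one$factor, 1.5, tolerance = 0.03)

  exact <- bootstrap_sum(list(lnq(10, 1), lnq(30, 1)), n_samples = 100,
                         seed = 1)
  expect_lnq_equal(exact, 40, 1)

  expect_error(bootstrap_sum(list(), seed = 1), "non-empty")
  expect_error(bootstrap_sum(list(lnq(1, 2)), n_samples = 1, seed = 1), ">= 2")
  expect_error(bootstrap_sum(list(lnq(1, 2))), "seed")
})

test_that("bootstrap_sum matches a brute-force Monte-Carlo oracle", {
  # oracle: direct summation of 1e6 lognormal draws, summarized on log scale
  qs <- list(lnq(100, 1.5), lnq(100, 1.5))
  oracle <- withr::with_seed(99, {
    sums <- rlnorm(1e6, log(100), log(1.5)) + rlnorm(1e6, log(100), log(1.5))
    exp(mean(log(sums)))
  })
  boot <- bootstrap_sum(qs, n_samples = 1e4, seed = 5)
  expect_equal(boot$median, oracle, tolerance = 0.02)

  # 2-5 heterogeneous summands
  qs2 <- list(lnq(10, 1.3), lnq(50, 2), lnq(5, 1.1), lnq(20, 1.6))
  oracle2 <- withr::with_seed(98, {
    draws <- sapply(qs2, function(q) rlnorm(1e6, log(q$median), log(q$factor)))
    exp(mean(log(rowSums(draws))))
  })
  boot2 <- bootstrap_sum(qs2, n_samples = 1e4, seed = 6)
  expect_equal(boot2$median, oracle2, tolerance = 0.02)
})

test_that("stochastic operations are bitwise reproducible under a seed", {
  a <- bootstrap_sum(list(lnq(3, 1.5), lnq(4, 1.2)), seed = 123)
  b <- bootstrap_sum(list(lnq(3, 1.5), lnq(4, 1.2)), seed = 123)
  expect_identical(a, b)
  u1 <- apply_uniform_factor(lnq(10, 1.3), seed = 77)
  u2 <- apply_uniform_factor(lnq(10, 1.3), seed = 77)
  expect_identical(u1, u2)
  expect_false(identical(u1, apply_uniform_factor(lnq(10, 1.3), seed = 78)))
})

test_that("apply_uniform_factor covers identity and degenerate ranges", {
  x <- lnq(1000, 1.4)
  id <- apply_uniform_factor(x, low = 1, high = 1, n_iter = 1e4, seed = 2)
  expect_equal(id$median, 1000, tolerance = 0.02)
  expect_equal(id$factor, 1.4, tolerance = 0.02)

  scaled <- apply_uniform_factor(lnq(1000, 1), 1.5, 1.5, n_iter = 100,
                                 seed = 2)
  expect_lnq_equal(scaled, 1500, 1, tol = 1e-9)

  expect_error(apply_uniform_factor(x, 2, 1, seed = 1), "exceed")
  expect_error(apply_uniform_factor(x, -1, 2, seed = 1), "non-negative")
  expect_error(apply_uniform_factor(x, 1, 2), "seed")
})

test_that("apply_uniform_factor matches a brute-force oracle on [1, 2]", {
  oracle <- withr::with_seed(101, {
    exp(mean(log(1000 * runif(1e6, 1, 2))))
  })
  fitted <- apply_uniform_factor(lnq(1000, 1), 1, 2, n_iter = 1e5, seed = 8)
  expect_equal(fitted$median, oracle, tolerance = 0.02)
  # analytic geometric mean of U(1,2): exp(2 ln 2 - 1)
  expect_equal(oracle / 1000, exp(2 * log(2) - 1), tolerance = 0.005)
})
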