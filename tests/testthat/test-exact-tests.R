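test_that("exact two-proportion Bayes factor matches the integral oracle", {
  # minimal case has the closed value 2/3
  expect_equal(two_prop_bf01_exact(two_by_two(1, 0, 0, 1))$bf01, 2 / 3,
               tolerance = 1e-12)
  # exhaustive over small totals
  for (tot in 2:16) {
    splits <- expand.grid(x = 0:tot, y = 0:tot, xp = 0:tot, yp = 0:tot)
    splits <- splits[rowSums(splits) == tot &
                       splits$x + splits$y >= 1 & splits$xp + splits$yp >= 1, ]
    idx <- seq_len(nrow(splits))
    if (length(idx) > 40) {
      set.seed(tot)
      idx <- sample(idx, 40)
    }
    for (i in idx) {
      s <- splits[i, ]
      expect_equal(two_prop_bf01_exact(two_by_two(s$x, s$y, s$xp, s$yp))$bf01,
                   oracle_two_prop_bf01(s$x, s$y, s$xp, s$yp),
                   tolerance = 1e-8)
    }
  }
  # random larger cases up to the quadrature oracle's comfort zone
  set.seed(42)
  for (rep in 1:200) {
    tot <- sample(17:60, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    x <- cuts[1]; y <- cuts[2] - cuts[1]
    xp <- cuts[3] - cuts[2]; yp <- tot - cuts[3]
    if (x + y < 1 || xp + yp < 1) next
    expect_equal(two_prop_bf01_exact(two_by_two(x, y, xp, yp))$bf01,
                 oracle_two_prop_bf01(x, y, xp, yp), tolerance = 1e-8)
  }
})

test_that("log-gamma evaluation is exact against cancelled factorials", {
  set.seed(7)
  for (rep in 1:100) {
    tot <- sample(4:200, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    x <- cuts[1]; y <- cuts[2] - cuts[1]
    xp <- cuts[3] - cuts[2]; yp <- tot - cuts[3]
    if (x + y < 1 || xp + yp < 1) next
    expect_equal(two_prop_bf01_exact(two_by_two(x, y, xp, yp))$bf01,
                 oracle_two_prop_factorial(x, y, xp, yp), tolerance = 1e-12)
  }
})

test_that("asymptotic two-proportion form reproduces its table and converges", {
  expect_equal(two_prop_bf01_asymptotic(two_by_two(20, 20, 20, 20))$bf01,
               3.57, tolerance = 0.005)
  expect_equal(two_prop_bf01_asymptotic(two_by_two(5000, 5000, 5000, 5000))$bf01,
               56.4, tolerance = 0.02)
  # null-consistent data: zero exponent, bf01 equals the outside factor
  res <- two_prop_bf01_asymptotic(two_by_two(10, 20, 20, 40))
  expect_identical(res$exponent, 0)
  expect_equal(res$bf01, res$outside_factor)
  # exact and asymptotic agree within 5% for balanced designs, margins >= 40
  for (half in c(20, 50, 100)) {
    ex <- two_prop_bf01_exact(two_by_two(half, half, half, half))$bf01
    as_ <- two_prop_bf01_asymptotic(two_by_two(half, half, half, half))$bf01
    expect_lt(abs(ex / as_ - 1), 0.05)
  }
  # and the relative error shrinks along N in {40, 100, 200, 400}
  relerr <- vapply(c(40, 100, 200, 400) / 2, function(half) {
    abs(two_prop_bf01_exact(two_by_two(half, half, half, half))$bf01 /
          two_prop_bf01_asymptotic(two_by_two(half, half, half, half))$bf01 - 1)
  }, numeric(1))
  expect_true(all(diff(relerr) < 0))
  expect_error(two_prop_bf01_asymptotic(two_by_two(0, 3, 0, 5)), "margins")
})

test_that("two-proportion Bayes factors respect the problem symmetries", {
  cases <- list(c(3, 9, 7, 2), c(20, 20, 13, 27), c(1, 5, 5, 1))
  for (cs in cases) {
    for (f in list(two_prop_bf01_exact, two_prop_bf01_asymptotic)) {
      base <- f(two_by_two(cs[1], cs[2], cs[3], cs[4]))$log_bf01
      # swap the two samples
      expect_equal(f(two_by_two(cs[3], cs[4], cs[1], cs[2]))$log_bf01, base,
                   tolerance = 1e-12)
      # relabel success/failure in both samples simultaneously
      expect_equal(f(two_by_two(cs[2], cs[1], cs[4], cs[3]))$log_bf01, base,
                   tolerance = 1e-12)
    }
  }
  expect_error(two_by_two(0, 0, 1, 1), "at least one")
  expect_error(two_by_two(-1, 2, 1, 1), "non-negative")
})

test_that("critical difference reproduces the equal-split table column", {
  expect_lt(abs(two_prop_critical_diff(40) - 14.3), 0.1)
  expect_lt(abs(two_prop_critical_diff(1000) - 107.4), 0.2)
  expect_equal(two_prop_critical_diff(4), sqrt(8 * log(4 / pi)),
               tolerance = 1e-12)
  expect_error(two_prop_critical_diff(2), "no crossing")
  expect_error(two_prop_critical_diff(41), "even")
  # the full-formula root exists and is close to (but below) the convention
  d_full <- two_prop_critical_diff(40, convention = "full")
  expect_lt(abs(d_full - 14.27) / 14.27, 0.02)
})

test_that("1938 t-test Bayes factor reproduces the 5% table and its limits", {
  expect_equal(ttest_bf01_1938(fisher_5pct_t(4), 5)$bf01, 0.610,
               tolerance = 0.002)
  expect_equal(ttest_bf01_1938(fisher_5pct_t(9), 10)$bf01, 0.522,
               tolerance = 0.002)
  expect_equal(ttest_bf01_1938(0, 5)$bf01, sqrt(10 / pi), tolerance = 1e-12)
  expect_warning(ttest_bf01_1938(1, 3), "inaccurate")
  expect_error(ttest_bf01_1938(1, 1), "at least 2")
  tab <- table3(c(5, 10))
  expect_equal(tab$display, c(0.610, 0.522))
})

test_that("at fixed t the t-test Bayes factor eventually rises with n, and falls in |t|", {
  # the paradox: K at t = 1.96 grows without bound along n
  ns <- c(10, 100, 1000, 10000, 100000)
  ks <- vapply(ns, function(n) ttest_bf01_1938(1.96, n)$log_bf01, numeric(1))
  expect_true(all(diff(ks) > 0))
  # at fixed n, K strictly decreases in |t|
  ts <- seq(0, 6, by = 0.5)
  kt <- vapply(ts, function(t) ttest_bf01_1938(t, 30)$log_bf01, numeric(1))
  expect_true(all(diff(kt) < 0))
  expect_equal(ttest_bf01_1938(-2, 30)$bf01, ttest_bf01_1938(2, 30)$bf01)
})

test_that("large-n critical t^2 matches log(2n/pi) and the exact root drifts at small n", {
  expect_equal(sqrt(ttest_critical_tsq_large_n(100000)), 3.326,
               tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(ttest_critical_tsq_large_n(ceiling(pi * exp(1) / 2)),
               log(2 * ceiling(pi * exp(1) / 2) / pi), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ttest_critical_tsq_large_n(500),
               critical_ratio(2 / pi, 500)^2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(ttest_critical_tsq_large_n(500), "approximation"),
                   "large-n")
  # exact K = 1 root at n = 8 differs measurably from the approximation
  exact_root <- uniroot(function(t) ttest_bf01_1938(t, 8)$log_bf01,
                        c(0.1, 10), tol = 1e-10)$root
  approx_root <- sqrt(ttest_critical_tsq_large_n(8))
  expect_gt(abs(exact_root - approx_root), 0.05)
})

test_that("two-sided 5% t critical values behave like the t distribution", {
  expect_equal(fisher_5pct_t(4), 2.776, tolerance = 0.001)
  expect_equal(fisher_5pct_t(9), 2.262, tolerance = 0.001)
  expect_equal(fisher_5pct_t(1e9), qnorm(0.975), tolerance = 1e-4)
  dfs <- c(1, 2, 5, 10, 50, 500)
  crit <- vapply(dfs, fisher_5pct_t, numeric(1))
  expect_true(all(diff(crit) < 0))
  expect_true(all(crit > qnorm(0.975)))
  expect_error(fisher_5pct_t(0), ">= 1")
})

test_that("uniform-departure test has the chi-square exponent and rising K=1 line", {
  expect_equal(uniform_departure_bf01(100, 0, 1)$bf01, sqrt(100 / (2 * pi)),
               tolerance = 1e-12)
  res <- uniform_departure_bf01(50, 0.3, 2)
  expect_equal(res$chisq, 50 * 0.09)
  expect_equal(res$exponent, -res$chisq / 2)
  expect_equal(res$bf01, sqrt(50 / (2 * pi)) * 2 * exp(-res$chisq / 2),
               tolerance = 1e-12)
  expect_error(uniform_departure_bf01(10, 0.1, c = 0), "positive")
  # chi^2 needed for K = 1 increases with n at fixed c
  chisq_k1 <- vapply(c(10, 100, 1000, 10000), function(n) {
    uniroot(function(ch) {
      uniform_departure_bf01(n, sqrt(ch / n), 1)$log_bf01
    }, c(1e-8, 100), tol = 1e-10)$root
  }, numeric(1))
  expect_true(all(diff(chisq_k1) > 0))
})
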