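# Independent oracles, deliberately brute-force and kept apart from the
# package's own code paths.

# Two-proportion Bayes factor by numerical integration of the marginal
# likelihoods: uniform prior on one shared proportion (null) vs independent
# uniform priors (alternative). Binomial coefficients cancel in the ratio.
oracle_two_prop_bf01 <- function(x, y, xp, yp) {
  marg0 <- integrate(function(th) dbinom(x, x + y, th) * dbinom(xp, xp + yp, th),
                     0, 1, rel.tol = 1e-12)$value
  m1a <- integrate(function(th) dbinom(x, x + y, th), 0, 1,
                   rel.tol = 1e-12)$value
  m1b <- integrate(function(th) dbinom(xp, xp + yp, th), 0, 1,
                   rel.tol = 1e-12)$value
  marg0 / (m1a * m1b)
}

# Exact-cancellation oracle for the factorial ratio: rewrite it as a product
# of binomial coefficients (computed by choose(), accurate to double
# precision after internal cancellation) times a small rational factor.
oracle_two_prop_factorial <- function(x, y, xp, yp) {
  N <- x + y + xp + yp
  choose(x + xp, x) * choose(y + yp, y) / choose(N, x + y) *
    (x + y + 1) * (xp + yp + 1) / (N + 1)
}

# Brute-force trapezoid integration of the Cauchy-prior t marginal on a wide
# fixed grid (delta in [-15, 15], 2e5 nodes).
oracle_bf10_cauchy_trapezoid <- function(t, n, scale = 1 / sqrt(2),
                                         nodes = 2e5) {
  delta <- seq(-15, 15, length.out = nodes)
  f <- suppressWarnings(dt(t, df = n - 1, ncp = delta * sqrt(n))) *
    dcauchy(delta, 0, scale)
  f[!is.finite(f)] <- 0
  h <- delta[2] - delta[1]
  marg <- h * (sum(f) - (f[1] + f[nodes]) / 2)
  marg / dt(t, df = n - 1)
}

# Peri-null Bayes factor as a ratio of normal marginals, each obtained by
# integrating N(z; delta*sqrt(n), 1) against the corresponding normal prior.
oracle_perinull_bf01 <- function(z, n, g0, g1) {
  marg <- function(g) {
    integrate(function(d) dnorm(z, d * sqrt(n), 1) * dnorm(d, 0, sqrt(g)),
              -Inf, Inf, rel.tol = 1e-12)$value
  }
  marg(g0) / marg(g1)
}

# Numeric root of sqrt(A n) exp(-z^2/2) = 1, independent of the closed form.
oracle_critical_ratio <- function(A, n) {
  uniroot(function(z) 0.5 * log(A * n) - z^2 / 2, c(1e-12, 50),
          tol = 1e-12)$root
}

# Grid minimization of the weighted error objective.
oracle_weighted_threshold <- function(lambda, n, g, grid = seq(0, 10, 1e-4)) {
  sd1 <- sqrt(1 + n * g)
  obj <- lambda * 2 * pnorm(grid, lower.tail = FALSE) +
    (pnorm(grid / sd1) - pnorm(-grid / sd1))
  grid[which.min(obj)]
}
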