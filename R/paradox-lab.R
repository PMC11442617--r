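#' Exact two-sided binomial tail probability
#'
#' Doubles the smaller exact tail, capped at 1: for a fair null (`p0 = 1/2`,
#' the case of all the coin and urn examples) this coincides with summing
#' probabilities of outcomes at least as extreme on both sides. No normal
#' approximation is used.
#'
#' @param k observed number of successes (0 <= k <= n).
#' @param n number of trials.
#' @param p0 null proportion in (0, 1); default 1/2.
#' @return The two-sided p value in `[0, 1]`.
#' @examples
#' binom_two_sided_p(120, 200)  # about 0.006
#' @export
binom_two_sided_p <- function(k, n, p0 = 0.5) {
  n <- check_n_obs(n)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) ||
      k != round(k) || k < 0 || k > n) {
    stop("'k' must be an integer between 0 and n")
  }
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1) {
    stop("'p0' must be strictly between 0 and 1")
  }
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Construct a large-n sample whose small p value supports the null
#'
#' The coin-tossing demonstration: a rival simple hypothesis puts the success
#' probability at `0.5 + epsilon`; choose the number of tosses `n` so that a
#' success count of `round(n * (0.5 + epsilon/7))` -- a sample proportion much
#' closer to 1/2 than to the rival value -- attains a two-sided tail
#' probability at or below `target_p`. The returned proportion then supports
#' the null against the rival even though the p value is "significant".
#'
#' The search returns the smallest `n` whose rounded success count attains
#' `p <= target_p`; the attained p is reported so specific published
#' endpoints can be checked without relying on the search convention.
#'
#' @param epsilon rival's excess success probability, in (0, 0.5).
#' @param target_p tail-probability target; default 0.01.
#' @param n_max search cap.
#' @return A list with `n`, `k`, `attained_p` and `proportion`.
#' @examples
#' simplissimus_construct(0.14)
#' @export
simplissimus_construct <- function(epsilon, target_p = 0.01, n_max = 1e6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0 || epsilon >= 0.5) {
    stop("'epsilon' must be strictly between 0 and 0.5")
  }
  prop <- 0.5 + epsilon / 7
  for (n in seq_len(n_max)) {
    k <- round(n * prop)
    if (k <= n / 2) next  # rounding put the count at or below the centre
    p <- binom_two_sided_p(k, n, 0.5)
    if (p <= target_p) {
      return(list(n = n, k = k, attained_p = p, proportion = k / n))
    }
  }
  stop("no n <= n_max attains the target tail probability")
}

#' Log likelihood ratio of the null against a simple rival
#'
#' For `k` successes in `n` trials, the log likelihood ratio of the null
#' proportion `p0` over a simple alternative `theta1`:
#' `k log(p0/theta1) + (n - k) log((1 - p0)/(1 - theta1))`. Positive values
#' favour the null.
#'
#' @inheritParams binom_two_sided_p
#' @param theta1 rival proportion, strictly inside (0, 1).
#' @return The log likelihood ratio (null over rival).
#' @examples
#' simple_vs_simple_lr(8517, 16700, theta1 = 0.57)  # about +118
#' @export
simple_vs_simple_lr <- function(k, n, p0 = 0.5, theta1) {
  n <- check_n_obs(n)
  if (!is.numeric(theta1) || length(theta1) != 1L || theta1 <= 0 ||
      theta1 >= 1) {
    stop("'theta1' must be strictly between 0 and 1")
  }
  if (!is.numeric(k) || k < 0 || k > n || k != round(k)) {
    stop("'k' must be an integer between 0 and n")
  }
  k * log(p0 / theta1) + (n - k) * log((1 - p0) / (1 - theta1))
}

#' Best alternative composition of a finite urn
#'
#' An urn holds `n_balls` balls, some white; the null composition is an even
#' split. Among all other compositions `w in {0, ..., n_balls}` find the one
#' with the highest likelihood for `k` white draws out of `n` (with
#' replacement), and report the log likelihood ratio of the null against that
#' best rival. A mixed-colour sample gives the pure compositions zero
#' likelihood, so they never win (and with only two balls the null is
#' infinitely supported). With a large `n` and a sample proportion near 1/2
#' the ratio is large and positive: a "significant" tail area
#' notwithstanding, no admissible alternative explains the data better than
#' the even split.
#'
#' @inheritParams binom_two_sided_p
#' @param n_balls even number of balls in the urn (>= 2).
#' @return A list with `w_best` (best rival composition),
#'   `log_lr_null_vs_best` (positive favours the null) and the per-composition
#'   log likelihoods.
#' @examples
#' bag_best_alternative(9690, 19000, n_balls = 10)
#' @export
bag_best_alternative <- function(k, n, n_balls = 10) {
  n <- check_n_obs(n)
  n_balls <- check_n_obs(n_balls, min = 2)
  if (n_balls %% 2 != 0) {
    stop("'n_balls' must be even (the null composition is an even split)")
  }
  if (!is.numeric(k) || k < 0 || k > n || k != round(k)) {
    stop("'k' must be an integer between 0 and n")
  }
  w <- setdiff(0:n_balls, n_balls / 2)
  loglik <- function(theta) {
    stats::dbinom(k, n, theta, log = TRUE)
  }
  ll <- vapply(w / n_balls, loglik, numeric(1))
  best <- which.max(ll)
  list(
    w_best = w[best],
    log_lr_null_vs_best = loglik(0.5) - ll[best],
    compositions = w,
    log_likelihoods = ll
  )
}

#' Rejection threshold minimizing a weighted sum of error rates
#'
#' With the prior under the alternative calibrated to the world frequency of
#' real effects -- here a zero-mean normal with variance `g` on the
#' standardized effect -- the marginal distribution of the z statistic under
#' the alternative is Normal(0, 1 + n g). The symmetric threshold `c`
#' minimizing `lambda * alpha(c) + beta(c)`, with
#' `alpha(c) = 2 (1 - Phi(c))` and `beta(c) = P(|Z| < c)` under the marginal,
#' is found by one-dimensional minimization. For `lambda = 1` it coincides
#' with the K = 1 threshold of [pointnull_z_bf01()]: minimizing total errors
#' and drawing the line at even posterior odds are the same rule.
#'
#' @param lambda positive weight on the Type I error rate.
#' @param n_obs sample size.
#' @param g prior variance of the standardized effect under the alternative.
#' @return The positive threshold `c` (in standard-error units).
#' @examples
#' weighted_error_threshold(1, 99, 1)
#' @export
weighted_error_threshold <- function(lambda, n_obs, g) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("'lambda' must be a positive number")
  }
  n_obs <- check_n_obs(n_obs)
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0) {
    stop("'g' must be a positive number")
  }
  sd1 <- sqrt(1 + n_obs * g)
  objective <- function(cc) {
    lambda * 2 * stats::pnorm(cc, lower.tail = FALSE) +
      (stats::pnorm(cc / sd1) - stats::pnorm(-cc / sd1))
  }
  # coarse scan first: the objective is flat (= 1) far outside the
  # informative region, where golden-section search alone can stall
  grid <- seq(0, 60, by = 0.05)
  cc0 <- grid[which.min(objective(grid))]
  opt <- stats::optimize(objective, c(max(cc0 - 0.1, 0), cc0 + 0.1),
                         tol = 1e-10)
  if (!is.finite(opt$minimum)) stop("threshold minimization failed")
  cc <- opt$minimum
  # polish with the first-order condition lambda * phi(c) = phi_marginal(c):
  # golden-section localization alone is noisy at the 1e-6 level
  deriv <- function(x) {
    -2 * lambda * stats::dnorm(x) + 2 * stats::dnorm(x / sd1) / sd1
  }
  lohi <- c(max(cc - 0.1, 1e-12), cc + 0.1)
  if (is.finite(deriv(lohi[1])) && is.finite(deriv(lohi[2])) &&
      sign(deriv(lohi[1])) != sign(deriv(lohi[2]))) {
    cc <- stats::uniroot(deriv, lohi, tol = 1e-12)$root
  }
  cc
}

#' Construct a paradox certificate
#'
#' Finds the smallest sample size at which a result sitting exactly on the
#' two-sided significance boundary -- a result every fixed-alpha tester
#' rejects -- carries Bayes-factor support for the null of at least
#' `target_bf01`. The statistic is held at the alpha boundary, the least
#' favourable rejection point, so the returned n is a lower bound over all
#' rejected data sets.
#'
#' @param alpha significance level in (0, 1).
#' @param prior a [prior_spec]: `normal_prior(g)` pairs with the z test,
#'   `cauchy_prior(r)` with the t test.
#' @param target_bf01 required Bayes factor in favour of the null (> 1).
#' @param test `"z_normal_prior"` or `"t_cauchy"`; defaults to the test
#'   matching the prior family.
#' @param n_max cap on the doubling search.
#' @return A list with `n`, `statistic`, `bf01`, and the `alpha`/`test` used;
#'   re-evaluating the named Bayes factor at (`n`, `statistic`) reproduces
#'   `bf01`.
#' @examples
#' paradox_construct(0.05, normal_prior(1), 10)  # n about 4700
#' @export
paradox_construct <- function(alpha, prior, target_bf01,
                              test = NULL, n_max = 2^40) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be strictly between 0 and 1")
  }
  stopifnot(inherits(prior, "prior_spec"))
  if (!is.numeric(target_bf01) || length(target_bf01) != 1L ||
      target_bf01 <= 1) {
    stop("'target_bf01' must exceed 1")
  }
  if (is.null(test)) {
    test <- switch(prior$family,
                   normal = "z_normal_prior",
                   cauchy = "t_cauchy",
                   stop("no test matches a '", prior$family, "' prior; ",
                        "use a normal or Cauchy prior"))
  }
  test <- match.arg(test, c("z_normal_prior", "t_cauchy"))
  eval_at <- function(n) {
    if (test == "z_normal_prior") {
      z <- stats::qnorm(1 - alpha / 2)
      list(stat = z, bf01 = pointnull_z_bf01(z, n, prior$g)$bf01)
    } else {
      tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
      list(stat = tcrit,
           bf01 = bf10_cauchy(tcrit, n, scale = prior$r)$bf01)
    }
  }
  lo <- if (test == "t_cauchy") 2 else 1
  hi <- lo
  while (eval_at(hi)$bf01 < target_bf01) {
    lo <- hi
    hi <- hi * 2
    if (hi > n_max) {
      stop(sprintf(
        "target BF01 = %g unreachable within n <= %g (best found: %g)",
        target_bf01, n_max, eval_at(n_max)$bf01))
    }
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (eval_at(mid)$bf01 >= target_bf01) hi <- mid else lo <- mid
  }
  res <- eval_at(hi)
  list(n = hi, statistic = res$stat, bf01 = res$bf01, alpha = alpha,
       test = test)
}

#' Simulate a one-sample normal data set
#'
#' Fixture generator for end-to-end checks: `n_obs` draws from a normal with
#' mean `delta` (the true standardized effect, since the noise is standard
#' normal) and unit standard deviation, plus the derived one-sample t
#' statistic. Deterministic given `seed`; the caller's random-number state is
#' left untouched.
#'
#' @param n_obs number of observations (>= 2).
#' @param delta true standardized effect size.
#' @param seed integer seed recorded in the output.
#' @return A list with `sample`, `t` (a [t_statistic()]), `delta` and `seed`.
#' @examples
#' simulate_one_sample(50, 0.5, seed = 1)$t
#' @export
simulate_one_sample <- function(n_obs, delta = 0, seed = 1L) {
  n_obs <- check_n_obs(n_obs, min = 2)
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  x <- stats::rnorm(n_obs, mean = delta, sd = 1)
  tval <- mean(x) / (stats::sd(x) / sqrt(n_obs))
  list(sample = x, t = t_statistic(tval, n_obs), delta = delta, seed = seed)
}
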