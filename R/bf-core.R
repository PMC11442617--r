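#' Jeffreys's generic approximate Bayes factor for a uniform-range prior
#'
#' For a point estimate `a` with standard error `s`, when the alternative
#' spreads the new parameter uniformly over a range of width `m`, the
#' approximate Bayes factor in favour of the null is
#' `K = m / (sqrt(2*pi) * s) * exp(-a^2 / (2 s^2))`. Since `s` shrinks like
#' `1/sqrt(n)` while `m` is fixed, the outside factor grows like `sqrt(n)`:
#' the root of the Jeffreys-Lindley paradox.
#'
#' @param summary an [estimate_summary()], or a numeric estimate `a` (in which
#'   case `standard_error` and `n_obs` must be supplied).
#' @param prior a uniform-range [prior_spec], or the numeric width `m`.
#' @param standard_error,n_obs used only when `summary` is numeric.
#' @return A [`bf_result`][new_bf_result] with the outside factor and
#'   exponent populated; evaluated in log space.
#' @examples
#' generic_bf01(0, 1, uniform_prior(sqrt(2 * pi)))  # BF01 = 1
#' @export
generic_bf01 <- function(summary, standard_error = NULL, prior = NULL,
                         n_obs = 1L) {
  if (!inherits(summary, "estimate_summary")) {
    summary <- estimate_summary(summary, standard_error, n_obs)
  } else if (inherits(standard_error, "prior_spec") ||
             is.numeric(standard_error)) {
    # generic_bf01(summary, prior) calling pattern
    prior <- standard_error
  }
  if (is.numeric(prior)) prior <- uniform_prior(prior)
  stopifnot(inherits(prior, "prior_spec"))
  if (prior$family != "uniform_range") {
    stop("generic_bf01 requires a uniform-range prior")
  }
  a <- summary$estimate
  s <- summary$standard_error
  log_outside <- log(prior$m) - 0.5 * log(2 * pi) - log(s)
  exponent <- -a^2 / (2 * s^2)
  new_bf_result(log_outside + exponent, log_outside, exponent,
                method = "generic uniform-range approximation")
}

#' Generic sqrt(A n) Bayes factor form
#'
#' The common large-sample shape of Jeffreys's tests:
#' `BF01 = sqrt(A * n) * exp(-ratio^2 / 2)`, where `ratio` is the estimate in
#' units of its standard error and `A` is a test-specific constant, usually
#' of order 1 (A = 2/pi in the least-squares case).
#'
#' @param A positive test-specific constant.
#' @param n_obs number of observations.
#' @param ratio estimate divided by its standard error.
#' @return A [`bf_result`][new_bf_result] with components populated.
#' @examples
#' sqrt_An_bf01(2 / pi, 100, 2)
#' @export
sqrt_An_bf01 <- function(A, n_obs, ratio) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0) {
    stop("'A' must be a positive number")
  }
  n_obs <- check_n_obs(n_obs)
  stopifnot(is.numeric(ratio), length(ratio) == 1L, is.finite(ratio))
  log_outside <- 0.5 * (log(A) + log(n_obs))
  exponent <- -ratio^2 / 2
  new_bf_result(log_outside + exponent, log_outside, exponent,
                method = "generic sqrt(A n) form")
}

#' Critical ratio where the generic Bayes factor crosses 1
#'
#' Solves `sqrt(A n) * exp(-z^2 / 2) = 1` in closed form: `z = sqrt(log(A n))`.
#' This is the multiple of the standard error at which the evidence switches
#' from favouring the null to favouring the alternative; it grows like
#' `sqrt(log n)` rather than staying constant.
#'
#' @inheritParams sqrt_An_bf01
#' @return The positive critical ratio.
#' @examples
#' critical_ratio(2 / pi, 100)  # about 2.04
#' @export
critical_ratio <- function(A, n_obs) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0) {
    stop("'A' must be a positive number")
  }
  n_obs <- check_n_obs(n_obs)
  An <- A * n_obs
  if (An <= 1) {
    msg <- if (An < 1) {
      "no crossing: sqrt(A*n) < 1, so BF01 < 1 for every ratio and BF01 = 1 cannot be reached"
    } else {
      "no positive crossing: sqrt(A*n) = 1, so BF01 = 1 only at ratio 0 and BF01 > 1 cannot be reached"
    }
    stop(msg)
  }
  sqrt(log(An))
}

#' Least-squares critical-ratio table
#'
#' For each sample size, the ratio of a least-squares estimate to its
#' standard error that makes the Bayes factor equal 1, from the criterion
#' `b^2 / sigma_b^2 > log(2n / pi)` (the A = 2/pi case of [critical_ratio()]).
#'
#' @param n_list positive integer sample sizes, each with `2n/pi > 1`.
#' @return A data frame with columns `n`, `critical_ratio` (full precision)
#'   and `display` (rounded to 2 decimals, matching the classical table).
#' @examples
#' table2(c(5, 10, 100, 100000))
#' @export
table2 <- function(n_list = c(5, 10, 20, 50, 100, 200, 500, 1000, 2000,
                              5000, 10000, 20000, 50000, 100000)) {
  cr <- vapply(n_list, function(n) critical_ratio(2 / pi, n), numeric(1))
  data.frame(n = n_list, critical_ratio = cr, display = round(cr, 2))
}

#' Calibrate a p value to a Bayes factor
#'
#' Converts a two-sided p value at sample size `n_obs` into the test statistic
#' it implies (upper p/2 quantile of the reference distribution) and evaluates
#' the matching Bayes factor. This makes the recurring comparison computable:
#' at moderate n the 5% point corresponds to a Bayes factor near 1/2, while at
#' large n the same p value yields BF01 > 1 -- a "significant" result that is
#' evidence for the null.
#'
#' @param p two-sided p value in (0, 1).
#' @param n_obs number of observations.
#' @param test which Bayes factor to evaluate: `"t_jeffreys1938"` (the 1938
#'   one-sample t form, [ttest_bf01_1938()]), `"z_normal_prior"` (normal prior
#'   on the standardized effect, [pointnull_z_bf01()]), or `"t_cauchy"`
#'   (Cauchy prior, [bf10_cauchy()]).
#' @param g prior variance for `"z_normal_prior"` (default 1).
#' @param scale Cauchy prior scale for `"t_cauchy"` (default `1/sqrt(2)`).
#' @return A [`bf_result`][new_bf_result].
#' @examples
#' calibrate_p_to_bf(0.05, 10, "t_jeffreys1938")  # BF01 about 0.52
#' @export
calibrate_p_to_bf <- function(p, n_obs,
                              test = c("t_jeffreys1938", "z_normal_prior",
                                       "t_cauchy"),
                              g = 1, scale = 1 / sqrt(2)) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop("'p' must be a number strictly between 0 and 1")
  }
  test <- match.arg(test)
  n_obs <- check_n_obs(n_obs)
  switch(test,
    t_jeffreys1938 = {
      tcrit <- stats::qt(1 - p / 2, df = n_obs - 1)
      ttest_bf01_1938(tcrit, n_obs)
    },
    z_normal_prior = {
      zcrit <- stats::qnorm(1 - p / 2)
      pointnull_z_bf01(zcrit, n_obs, g1 = g)
    },
    t_cauchy = {
      tcrit <- stats::qt(1 - p / 2, df = n_obs - 1)
      bf10_cauchy(tcrit, n_obs, scale = scale)
    }
  )
}
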