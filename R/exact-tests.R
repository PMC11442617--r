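#' Exact two-proportion Bayes factor
#'
#' Posterior odds of a shared population proportion (null) against two
#' independent proportions (alternative), under uniform priors on all
#' proportions and equal prior model odds:
#' `BF01 = (x+x')! (y+y')! (x+y+1)! (x'+y'+1)! /
#'         (x! y! x'! y'! (x+x'+y+y'+1)!)`.
#' Evaluated via `lgamma`, not literal factorials, so large counts are exact
#' to double precision.
#'
#' @param counts a [two_by_two()] object, or the count `x` (then `y`, `xp`,
#'   `yp` must be given).
#' @param y,xp,yp counts, used when `counts` is numeric.
#' @return A [`bf_result`][new_bf_result] (no outside/exponent decomposition).
#' @examples
#' two_prop_bf01_exact(two_by_two(20, 20, 20, 20))
#' @export
two_prop_bf01_exact <- function(counts, y = NULL, xp = NULL, yp = NULL) {
  if (!inherits(counts, "two_by_two")) counts <- two_by_two(counts, y, xp, yp)
  lf <- function(k) lgamma(k + 1)
  with(counts, {
    log_bf <- lf(x + xp) + lf(y + yp) + lf(x + y + 1) + lf(xp + yp + 1) -
      lf(x) - lf(y) - lf(xp) - lf(yp) - lf(x + xp + y + yp + 1)
    new_bf_result(log_bf, method = "two-proportion (exact)")
  })
}

#' Asymptotic two-proportion Bayes factor
#'
#' Large-sample approximation to [two_prop_bf01_exact()]:
#' outside factor `{(x+x'+y+y')(x+y)(x'+y') / (2 pi (x+x')(y+y'))}^(1/2)`,
#' exponent `-(x+x'+y+y')(xy'-x'y)^2 / (2 (x+x')(y+y')(x+y)(x'+y'))`.
#' The outside factor grows like sqrt(total), so null-concordant data support
#' the null more strongly the larger the samples.
#'
#' @inheritParams two_prop_bf01_exact
#' @return A [`bf_result`][new_bf_result] with components populated.
#' @examples
#' two_prop_bf01_asymptotic(two_by_two(20, 20, 20, 20))  # BF01 = 3.57
#' @export
two_prop_bf01_asymptotic <- function(counts, y = NULL, xp = NULL, yp = NULL) {
  if (!inherits(counts, "two_by_two")) counts <- two_by_two(counts, y, xp, yp)
  with(counts, {
    if (x + xp == 0 || y + yp == 0) {
      stop("degenerate margins: x + x' and y + y' must both be positive")
    }
    N <- x + y + xp + yp
    log_outside <- 0.5 * (log(N) + log(x + y) + log(xp + yp) -
                            log(2 * pi) - log(x + xp) - log(y + yp))
    cross <- x * yp - xp * y
    exponent <- -0.5 * N * cross^2 /
      ((x + xp) * (y + yp) * (x + y) * (xp + yp))
    new_bf_result(log_outside + exponent, log_outside, exponent,
                  method = "two-proportion (asymptotic)")
  })
}

#' Critical two-proportion difference
#'
#' With a first sample split evenly (`x = y = N/2`) and a second sample of the
#' same total `N`, the difference `d = x' - y'` needed to bring the asymptotic
#' posterior odds down to 1. Under the equal-split convention the variance
#' factors in the exponent are evaluated at `x' = y'`, giving the closed form
#' `d = sqrt(2 N log(N / pi))`; this convention reproduces the classical
#' table (e.g. 14.3 at N = 40). `convention = "full"` instead solves the full
#' asymptotic formula, in which the variance factors shift with `d`, by
#' numerical root finding.
#'
#' @param total even positive integer `N = x + y = x' + y'`; must exceed pi.
#' @param convention `"equal_split"` (default, closed form) or `"full"`.
#' @return The positive critical difference.
#' @examples
#' two_prop_critical_diff(40)  # about 14.27
#' @export
two_prop_critical_diff <- function(total,
                                   convention = c("equal_split", "full")) {
  convention <- match.arg(convention)
  N <- check_n_obs(total)
  if (N %% 2 != 0) stop("'total' must be an even integer")
  if (N <= pi) stop("no crossing: total must exceed pi for BF01 to reach 1")
  if (convention == "equal_split") {
    return(sqrt(2 * N * log(N / pi)))
  }
  f <- function(d) {
    xp <- (N + d) / 2
    yp <- (N - d) / 2
    log_outside <- 0.5 * (log(2 * N) + 2 * log(N) - log(2 * pi) -
                            log(N / 2 + xp) - log(N / 2 + yp))
    exponent <- -0.5 * 2 * N * ((N / 2) * d)^2 /
      ((N / 2 + xp) * (N / 2 + yp) * N * N)
    log_outside + exponent
  }
  stats::uniroot(f, c(1e-8, N - 1e-8), tol = 1e-10)$root
}

#' Jeffreys's 1938 t-test Bayes factor
#'
#' One-sample t-test Bayes factor in favour of the null:
#' `K = sqrt(2n/pi) * (1 + t^2/(n-1))^(-(n-3)/2)`, with `t^2 =
#' (n-1) * xbar^2 / sigma^2`. The form is approximate and may be appreciably
#' inaccurate for `n < 4` (a warning is issued for `n` of 2 or 3).
#'
#' @param stat a [t_statistic()], or the numeric t value (then `n_obs` must
#'   be given).
#' @param n_obs number of observations, when `stat` is numeric.
#' @return A [`bf_result`][new_bf_result] with the sqrt(2n/pi) outside factor
#'   and log of the power term as exponent.
#' @examples
#' ttest_bf01_1938(2.776, 5)  # the 5% point at n = 5: K about 0.61
#' @export
ttest_bf01_1938 <- function(stat, n_obs = NULL) {
  stat <- as_t_stat(stat, n_obs)
  n <- stat$n_obs
  if (n < 4) {
    warning("the 1938 t approximation may be appreciably inaccurate for n < 4")
  }
  log_outside <- 0.5 * (log(2) + log(n) - log(pi))
  exponent <- -0.5 * (n - 3) * log1p(stat$t^2 / (n - 1))
  new_bf_result(log_outside + exponent, log_outside, exponent,
                method = "one-sample t (1938 form)")
}

#' Large-n critical t-squared for the 1938 t test
#'
#' For K = 1 and large n the 1938 t-test Bayes factor gives the approximation
#' `t^2 = log(2n/pi)`; the squared critical statistic grows with log n while
#' the fixed-alpha threshold stays at 1.96^2. Consistent with
#' `critical_ratio(2/pi, n)^2`.
#'
#' @param n_obs number of observations with `2 n / pi > 1`.
#' @return The critical `t^2` (take the square root for the t scale). The
#'   result carries an attribute `"approximation"` = `"large-n"` as a
#'   reminder that the exact K = 1 root differs at small n.
#' @examples
#' sqrt(ttest_critical_tsq_large_n(100000))  # about 3.33
#' @export
ttest_critical_tsq_large_n <- function(n_obs) {
  tsq <- critical_ratio(2 / pi, n_obs)^2
  attr(tsq, "approximation") <- "large-n"
  tsq
}

#' Two-sided 5% critical value of the t distribution
#'
#' The upper 0.975 quantile of the central t distribution: the statistic at
#' which a two-sided test at the 5% level just rejects.
#'
#' @param df degrees of freedom (>= 1).
#' @return The positive critical t value.
#' @examples
#' fisher_5pct_t(4)  # 2.776
#' @export
fisher_5pct_t <- function(df) {
  if (!is.numeric(df) || length(df) != 1L || !is.finite(df) || df < 1) {
    stop("'df' must be a number >= 1")
  }
  stats::qt(0.975, df = df)
}

#' Uniform-departure Bayes factor
#'
#' Test of a continuous departure from a suggested (uniform) distribution of
#' chance: `BF01 = sqrt(n / (2 pi)) * c * exp(-n a0^2 / 2)`, where `a0` is the
#' maximum-likelihood departure amplitude (standard error `1/sqrt(n)`) and `c`
#' a problem-specific constant. The exponent is `-chi^2 / 2` with
#' `chi^2 = n a0^2`.
#'
#' @param n_obs number of observations.
#' @param a0 maximum-likelihood amplitude of the departure.
#' @param c positive problem constant.
#' @return A [`bf_result`][new_bf_result]; the additional element `chisq`
#'   holds `n * a0^2`.
#' @examples
#' uniform_departure_bf01(100, 0.1, 1)
#' @export
uniform_departure_bf01 <- function(n_obs, a0, c = 1) {
  n_obs <- check_n_obs(n_obs)
  stopifnot(is.numeric(a0), length(a0) == 1L, is.finite(a0))
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    stop("'c' must be a positive number")
  }
  chisq <- n_obs * a0^2
  log_outside <- 0.5 * (log(n_obs) - log(2 * pi)) + log(c)
  exponent <- -chisq / 2
  out <- new_bf_result(log_outside + exponent, log_outside, exponent,
                       method = "uniform-departure test")
  out$chisq <- chisq
  out
}

#' Table of K at the two-sided 5% t point
#'
#' For each sample size, the value of the 1938 t-test Bayes factor when the
#' observed t sits exactly at the two-sided 5% critical value with
#' `df = n - 1`. Around n = 10 the 5% point corresponds to K near 0.5 (2-to-1
#' odds for the alternative); at large n the same 5% point gives K > 1, i.e.
#' evidence for the null.
#'
#' @param n_list positive integer sample sizes (>= 2).
#' @return A data frame with columns `n`, `t_5pct`, `K` and `display`
#'   (K rounded to 3 decimals).
#' @examples
#' table3()
#' @export
table3 <- function(n_list = c(5, 6, 7, 8, 9, 10, 20, 30)) {
  t5 <- vapply(n_list, function(n) fisher_5pct_t(n - 1), numeric(1))
  K <- mapply(function(t, n) ttest_bf01_1938(t, n)$bf01, t5, n_list)
  data.frame(n = n_list, t_5pct = t5, K = K, display = round(K, 3))
}

#' Two-proportion illustration table
#'
#' For first samples split evenly with total `x + y = N` and second samples of
#' the same size, gives the maximum of the asymptotic posterior odds (attained
#' at `x' = y'`) and the difference `x' - y'` needed to bring the odds down to
#' unity (equal-split convention, see [two_prop_critical_diff()]).
#'
#' @param n_list even totals `N`.
#' @return A data frame with columns `total`, `max_bf01`, `critical_diff`,
#'   `scaled_diff` (critical difference over sqrt(N)).
#' @examples
#' table1(c(40, 100, 10000))
#' @export
table1 <- function(n_list = c(40, 100, 200, 400, 1000, 10000, 100000)) {
  max_bf <- vapply(n_list, function(N) {
    two_prop_bf01_asymptotic(two_by_two(N / 2, N / 2, N / 2, N / 2))$bf01
  }, numeric(1))
  cd <- vapply(n_list, two_prop_critical_diff, numeric(1))
  data.frame(total = n_list, max_bf01 = max_bf, critical_diff = cd,
             scaled_diff = cd / sqrt(n_list))
}
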