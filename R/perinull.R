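#' Pair of nested normal priors
#'
#' The peri-null construction replaces the point null by a narrow zero-mean
#' normal prior on the standardized effect (variance `g0`, the skeptic) and
#' keeps a wider zero-mean normal under the alternative (variance `g1`, the
#' proponent), with `0 < g0 < g1`.
#'
#' @param g0 skeptic's prior variance.
#' @param g1 proponent's prior variance; must exceed `g0`.
#' @return A list of class `"normal_prior_pair"`.
#' @examples
#' normal_prior_pair(0.1, 1)
#' @export
normal_prior_pair <- function(g0, g1) {
  if (!is.numeric(g0) || !is.numeric(g1) || length(g0) != 1L ||
      length(g1) != 1L || !is.finite(g0) || !is.finite(g1) || g0 <= 0) {
    stop("'g0' and 'g1' must be positive numbers")
  }
  if (g0 >= g1) stop("peri-null construction requires g0 < g1")
  structure(list(g0 = g0, g1 = g1), class = "normal_prior_pair")
}

as_prior_pair <- function(pair, g1) {
  if (inherits(pair, "normal_prior_pair")) return(pair)
  normal_prior_pair(pair, g1)
}

#' Peri-null Bayes factor for the z test
#'
#' For normally distributed data with known unit variance and nested normal
#' priors on the standardized effect (variances `g0 < g1`), the Bayes factor
#' of the narrow (peri-null) model over the wide one is
#' `BF01 = sqrt((1 + n g1)/(1 + n g0)) *
#'         exp((g0 - g1) n z^2 / (2 (1 + n g0)(1 + n g1)))`.
#' It equals 1 at n = 0 and, for z held at a fixed-alpha value, converges
#' monotonically from below to the bound `sqrt(g1/g0)` after an initial dip:
#' when `z > 1` the factor first drops below 1 at small n (some evidence for
#' the alternative) before rising towards the bound. The paradox survives
#' the removal of the point mass.
#'
#' `n_obs` is treated as a positive real here so that curves and limits are
#' smooth; n = 0 is allowed and returns exactly 1.
#'
#' @param z observed z statistic.
#' @param n_obs sample size (non-negative real).
#' @param pair a [normal_prior_pair()], or the numeric `g0` (then `g1` must
#'   be given).
#' @param g1 proponent's variance, when `pair` is numeric.
#' @return A [`bf_result`][new_bf_result] with the variance-ratio term as
#'   outside factor and the (non-positive) exponential term as exponent.
#' @examples
#' perinull_bf01(1.96, 1000, normal_prior_pair(0.05, 1))  # about 4.27
#' @export
perinull_bf01 <- function(z, n_obs, pair, g1 = NULL) {
  pair <- as_prior_pair(pair, g1)
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z))
  if (!is.numeric(n_obs) || length(n_obs) != 1L || !is.finite(n_obs) ||
      n_obs < 0) {
    stop("'n_obs' must be a non-negative number")
  }
  g0 <- pair$g0
  g1 <- pair$g1
  log_outside <- 0.5 * (log1p(n_obs * g1) - log1p(n_obs * g0))
  exponent <- (g0 - g1) * n_obs * z^2 /
    (2 * (1 + n_obs * g0) * (1 + n_obs * g1))
  new_bf_result(log_outside + exponent, log_outside, exponent,
                method = "peri-null z test")
}

#' Large-n limit of the peri-null Bayes factor
#'
#' With the statistic held at any fixed-alpha value, the peri-null Bayes
#' factor converges monotonically to `sqrt(g1 / g0)` as n grows: bounded, but
#' still in favour of the (peri-)null for any alpha.
#'
#' @inheritParams perinull_bf01
#' @return The positive limit `sqrt(g1/g0)`.
#' @examples
#' perinull_limit(normal_prior_pair(0.1, 1))  # sqrt(10)
#' @export
perinull_limit <- function(pair, g1 = NULL) {
  pair <- as_prior_pair(pair, g1)
  sqrt(pair$g1 / pair$g0)
}

#' Peri-null paradox curve
#'
#' Traces the peri-null Bayes factor along a grid of sample sizes with the z
#' statistic pinned at the significance boundary. The default convention
#' takes `z = qnorm(1 - alpha)` (the convention behind the published curves);
#' `"two_sided"` uses `z = qnorm(1 - alpha/2)`.
#'
#' @param alpha significance level in (0, 1).
#' @param pair a [normal_prior_pair()].
#' @param n_grid positive sample sizes (need not be integer).
#' @param z_convention `"paper"` (one-sided quantile, default) or
#'   `"two_sided"`.
#' @return A data frame of class `"paradox_curve"` with columns `n`, `z`,
#'   `bf01`; attributes record the prior pair, alpha and the limit.
#' @examples
#' perinull_curve(0.05, normal_prior_pair(0.1, 1), c(10, 100, 1000))
#' @export
perinull_curve <- function(alpha, pair, n_grid,
                           z_convention = c("paper", "two_sided")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be strictly between 0 and 1")
  }
  pair <- as_prior_pair(pair, NULL)
  if (length(n_grid) == 0) stop("'n_grid' must be non-empty")
  if (!is.numeric(n_grid) || any(!is.finite(n_grid)) || any(n_grid <= 0)) {
    stop("'n_grid' must contain positive sample sizes")
  }
  z_convention <- match.arg(z_convention)
  z <- if (z_convention == "paper") stats::qnorm(1 - alpha) else
    stats::qnorm(1 - alpha / 2)
  bf <- vapply(n_grid, function(n) perinull_bf01(z, n, pair)$bf01, numeric(1))
  structure(
    data.frame(n = n_grid, z = z, bf01 = bf),
    class = c("paradox_curve", "data.frame"),
    alpha = alpha, g0 = pair$g0, g1 = pair$g1,
    limit = perinull_limit(pair), z_convention = z_convention
  )
}

#' @export
print.paradox_curve <- function(x, ...) {
  cat("Peri-null paradox curve: alpha = ", attr(x, "alpha"),
      ", g0 = ", attr(x, "g0"), ", g1 = ", attr(x, "g1"),
      ", limit sqrt(g1/g0) = ", format(attr(x, "limit"), digits = 4),
      "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.paradox_curve <- function(x, ...) {
  graphics::plot(x$n, x$bf01, type = "l", log = "x",
                 xlab = "sample size n", ylab = "BF01 (peri-null)", ...)
  graphics::abline(h = attr(x, "limit"), lty = 2)
  graphics::abline(h = 1, col = "grey")
  invisible(x)
}

#' Point-null z-test Bayes factor with a normal prior
#'
#' The `g0 -> 0` limit of the peri-null form: a point null against a
#' zero-mean normal prior with variance `g1` on the standardized effect,
#' `BF01 = sqrt(1 + n g1) * exp(-g1 n z^2 / (2 (1 + n g1)))`. Unlike the
#' peri-null version this grows without bound (like sqrt(n)) when z is held
#' fixed.
#'
#' @param z observed z statistic.
#' @param n_obs sample size (non-negative real).
#' @param g1 prior variance (positive).
#' @return A [`bf_result`][new_bf_result] with components populated.
#' @examples
#' pointnull_z_bf01(0, 99, 1)  # sqrt(100) = 10
#' @export
pointnull_z_bf01 <- function(z, n_obs, g1 = 1) {
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z))
  if (!is.numeric(n_obs) || length(n_obs) != 1L || !is.finite(n_obs) ||
      n_obs < 0) {
    stop("'n_obs' must be a non-negative number")
  }
  if (!is.numeric(g1) || length(g1) != 1L || !is.finite(g1) || g1 <= 0) {
    stop("'g1' must be a positive number")
  }
  log_outside <- 0.5 * log1p(n_obs * g1)
  exponent <- -g1 * n_obs * z^2 / (2 * (1 + n_obs * g1))
  new_bf_result(log_outside + exponent, log_outside, exponent,
                method = "point-null z test, normal prior")
}
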