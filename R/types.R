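#' Bayes factor result
#'
#' Container returned by every Bayes-factor operation in the package. All
#' computation is carried out on the log scale; `bf01` and `bf10` are derived
#' from `log_bf01` (and may be `Inf`/`0` on the linear scale when the log is
#' extreme). For Jeffreys's approximate forms the multiplicative sqrt(n)-order
#' "outside factor" and the (non-positive) exponent of the exponential term
#' are reported separately, since the outside factor is what drives the
#' Jeffreys-Lindley paradox.
#'
#' @param log_bf01 log Bayes factor in favour of the null.
#' @param log_outside log of the outside factor, or `NA` when the form has no
#'   such decomposition (e.g. exact or quadrature-based Bayes factors).
#' @param exponent exponent of the exponential term, or `NA`.
#' @param method short label describing the originating test.
#'
#' @return An object of class `"bf_result"`: a list with elements `bf01`,
#'   `bf10`, `log_bf01`, `outside_factor`, `exponent` and `method`.
#' @keywords internal
new_bf_result <- function(log_bf01, log_outside = NA_real_,
                          exponent = NA_real_, method = "") {
  stopifnot(is.numeric(log_bf01), length(log_bf01) == 1L, !is.na(log_bf01))
  structure(
    list(
      bf01 = exp(log_bf01),
      bf10 = exp(-log_bf01),
      log_bf01 = log_bf01,
      outside_factor = if (is.na(log_outside)) NA_real_ else exp(log_outside),
      exponent = exponent,
      method = method
    ),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, digits = 4, ...) {
  cat("Bayes factor (", x$method, ")\n", sep = "")
  cat("  BF01 = ", format(x$bf01, digits = digits),
      "   BF10 = ", format(x$bf10, digits = digits),
      "   log BF01 = ", format(x$log_bf01, digits = digits), "\n", sep = "")
  if (!is.na(x$outside_factor)) {
    cat("  outside factor = ", format(x$outside_factor, digits = digits),
        "   exponent = ", format(x$exponent, digits = digits), "\n", sep = "")
  }
  invisible(x)
}

#' Summary of a point estimate
#'
#' Bundles a maximum-likelihood (or least-squares) point estimate, its
#' standard error, and the number of observations behind it -- the three
#' quantities entering Jeffreys's generic approximate Bayes factor.
#'
#' @param estimate point estimate of the test-relevant parameter.
#' @param standard_error its standard error; must be positive.
#' @param n_obs number of observations; must be a positive integer.
#' @return A list of class `"estimate_summary"`.
#' @examples
#' estimate_summary(0.3, 0.1, 25)
#' @export
estimate_summary <- function(estimate, standard_error, n_obs) {
  stopifnot(is.numeric(estimate), length(estimate) == 1L, is.finite(estimate))
  if (!is.numeric(standard_error) || length(standard_error) != 1L ||
      !is.finite(standard_error) || standard_error <= 0) {
    stop("'standard_error' must be a positive number")
  }
  n_obs <- check_n_obs(n_obs)
  structure(list(estimate = estimate, standard_error = standard_error,
                 n_obs = n_obs),
            class = "estimate_summary")
}

#' Prior on the test-relevant parameter under the alternative
#'
#' The alternative hypothesis spreads the new parameter over one of three
#' families: a uniform prior over a range of total width `m`, a zero-mean
#' normal with variance `g`, or a zero-centred Cauchy with scale `r`. The
#' prior's ordinate at zero, `f(0)`, must be strictly positive for a
#' significance test to be possible at all, and is what enters both
#' Jeffreys's outside factor and the Savage-Dickey density ratio.
#'
#' @param m total width of the uniform range; positive.
#' @param g variance of the zero-mean normal prior; positive.
#' @param r scale of the zero-centred Cauchy prior; positive.
#' @return A list of class `"prior_spec"` with elements `family` and the
#'   family's parameter.
#' @examples
#' uniform_prior(sqrt(2 * pi))
#' normal_prior(1)
#' cauchy_prior(1 / sqrt(2))
#' @name prior_spec
NULL

new_prior_spec <- function(family, value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0) {
    stop(sprintf("prior parameter '%s' must be a positive number", name))
  }
  out <- structure(list(family = family), class = "prior_spec")
  out[[name]] <- value
  out
}

#' @rdname prior_spec
#' @export
uniform_prior <- function(m) new_prior_spec("uniform_range", m, "m")

#' @rdname prior_spec
#' @export
normal_prior <- function(g) new_prior_spec("normal", g, "g")

#' @rdname prior_spec
#' @export
cauchy_prior <- function(r) new_prior_spec("cauchy", r, "r")

#' @rdname prior_spec
#' @param prior a `"prior_spec"` object.
#' @export
ordinate_at_zero <- function(prior) {
  stopifnot(inherits(prior, "prior_spec"))
  switch(prior$family,
         uniform_range = 1 / prior$m,
         normal = 1 / sqrt(2 * pi * prior$g),
         cauchy = 1 / (pi * prior$r),
         stop("unknown prior family"))
}

#' @export
print.prior_spec <- function(x, ...) {
  par <- setdiff(names(x), "family")
  cat("Prior on the test-relevant parameter: ", x$family, " (",
      par, " = ", format(x[[par]]), "), f(0) = ",
      format(ordinate_at_zero(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Two independent binomial samples
#'
#' Counts for the two-proportion problem: one sample gives `x` units with the
#' property and `y` without, the other gives `xp` and `yp`.
#'
#' @param x,y,xp,yp non-negative integer counts; each sample must contain at
#'   least one observation.
#' @return A list of class `"two_by_two"`.
#' @examples
#' two_by_two(20, 20, 13, 27)
#' @export
two_by_two <- function(x, y, xp, yp) {
  counts <- c(x = x, y = y, xp = xp, yp = yp)
  if (!all(is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (x + y < 1 || xp + yp < 1) {
    stop("each sample must contain at least one observation")
  }
  structure(as.list(counts), class = "two_by_two")
}

#' One-sample t statistic
#'
#' @param t observed t statistic.
#' @param n_obs number of observations (>= 2); degrees of freedom are
#'   `n_obs - 1` (one-sample design).
#' @return A list of class `"t_statistic"` with elements `t`, `n_obs`, `df`.
#' @examples
#' t_statistic(2.321, 20)
#' @export
t_statistic <- function(t, n_obs) {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  n_obs <- check_n_obs(n_obs)
  if (n_obs < 2) stop("'n_obs' must be at least 2 for a t statistic")
  structure(list(t = t, n_obs = n_obs, df = n_obs - 1L),
            class = "t_statistic")
}

# shared validation: positive integer sample size
check_n_obs <- function(n_obs, min = 1) {
  if (!is.numeric(n_obs) || length(n_obs) != 1L || !is.finite(n_obs) ||
      n_obs < min || n_obs != round(n_obs)) {
    stop(sprintf("'n_obs' must be an integer >= %d", min))
  }
  as.integer(n_obs)
}

# coerce (t, n) arguments: either a t_statistic or two numerics
as_t_stat <- function(t, n_obs) {
  if (inherits(t, "t_statistic")) return(t)
  t_statistic(t, n_obs)
}
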