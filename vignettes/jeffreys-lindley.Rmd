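---
title: "Bayes factors, sample size, and the Jeffreys-Lindley paradox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayes factors, sample size, and the Jeffreys-Lindley paradox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jlparadox)
```

## The model behind every function in this package

A hypothesis test here is always a comparison of two *marginal likelihoods*.
The null model $\mathcal{M}_0$ fixes the test-relevant parameter (a
difference, a regression coefficient, a standardized effect size) at zero;
the alternative $\mathcal{M}_1$ equips it with a prior $\pi(\theta)$ and
predicts the data by averaging the likelihood over that prior:

$$\mathrm{BF}_{01} = \frac{p(y \mid \mathcal{M}_0)}
  {\int f(y \mid \theta)\,\pi(\theta)\,\mathrm{d}\theta}.$$

Whenever the likelihood concentrates like $1/\sqrt{n}$ around an estimate
$a$ with standard error $s$, and the prior is flat on the scale of $s$ (a
uniform range of width $m$, say), the integral is approximately
$f(y\mid a)\cdot 2\pi^{1/2}\ldots$ — worked out, the Bayes factor takes the
shape used throughout the package:

$$\mathrm{BF}_{01} \approx
  \underbrace{\frac{m}{\sqrt{2\pi}\,s}}_{\text{outside factor},\ O(\sqrt n)}
  \exp\!\Big(-\frac{a^2}{2s^2}\Big).$$

The exponential term depends only on the standardized ratio $a/s$ — the
same quantity a significance test thresholds — but the outside factor grows
like $\sqrt n$. Intuitively, the prior must spread its bets over the whole
range $m$; observing $a$ within one standard error of zero is *exactly* what
$\mathcal{M}_0$ predicts but a lucky coincidence under $\mathcal{M}_1$, and
the coincidence becomes more remarkable as $s$ shrinks. The break-even
ratio solving $\mathrm{BF}_{01} = 1$ for the generic form
$\sqrt{An}\,e^{-z^2/2}$ is

$$z^* = \sqrt{\log(An)},$$

implemented in closed form by `critical_ratio()` (a numeric root-finder
cross-checks it in the tests). Because $z^*\to\infty$ while any fixed-level
test keeps its threshold constant, data can always be constructed that are
simultaneously "significant" and evidence *for* the null: the
Jeffreys-Lindley paradox. `paradox_construct()` does precisely that search
and returns a verifiable certificate (n, statistic, attained BF01).

## Concrete tests and their conventions

**Two proportions** (`two_prop_bf01_exact()`): uniform priors on a shared
proportion under $\mathcal{M}_0$ versus independent uniform priors under
$\mathcal{M}_1$ give a closed-form ratio of factorials, evaluated via
`lgamma`. The large-sample approximation (`two_prop_bf01_asymptotic()`)
exposes the outside factor and exponent separately. The classical
illustration table (`table1()`) reports, at equal splits $x=y$ with
$x'+y'=x+y=N$, the critical difference $x'-y'$ that brings the odds to 1.
Reproducing its printed values requires evaluating the variance factors of
the exponent *at the equal-split configuration*, which yields the closed
form $d=\sqrt{2N\log(N/\pi)}$ (14.27 at $N=40$, printed 14.3). Solving the
full asymptotic formula instead gives a root about 1% lower (14.13 at
$N=40$); it is available behind `convention = "full"`. The equal-split
convention is the default because it is the one the historical table used.

**One-sample t, 1938 form** (`ttest_bf01_1938()`):
$K=\sqrt{2n/\pi}\,(1+t^2/(n-1))^{-(n-3)/2}$, evaluated in log space via
`log1p`. The form is approximate; for $n<4$ a warning is issued (for
$n < 2$ an error). The companion table (`table3()`) evaluates $K$ at the
two-sided 5% critical $t$ with $n-1$ degrees of freedom, computed from the
modern t quantile function rather than from rounded historical tables;
the rows $n=20$ and $n=30$ consequently differ from the historical cells by
up to about 1.5%, while $n=5$ through $n=10$ reproduce to three decimals.

**Uniform departures** (`uniform_departure_bf01()`):
$K=\sqrt{n/2\pi}\,c\,e^{-na_0^2/2}$ with a problem-specific constant $c>0$
that the user must supply (the historical sources never tabulate it); the
exponent is $-\chi^2/2$ with $\chi^2=na_0^2$ since the standard error of
$a_0$ is $n^{-1/2}$. Only the qualitative property that the $K=1$ line of
$\chi^2$ rises with $n$ is asserted in the tests.

## The fully Bayesian version: the Cauchy-prior t test

Under $\mathcal{M}_1$ the standardized effect $\delta=\mu/\sigma$ has a
zero-centred Cauchy prior with scale $r=1/\sqrt2$ (the modern default; the
scale is an argument everywhere). The observed $t$ with $\nu=n-1$ degrees
of freedom has a noncentral-t likelihood with noncentrality
$\delta\sqrt n$ — the one-sample design; this parameterization is what
reproduces the published three-panel demonstration and is stated explicitly
here because it is easy to get wrong (a two-sample design would use a
different effective n).

Numerics: the marginal likelihood substitutes $\delta = r\tan\theta$, which
turns the Cauchy weight into a uniform weight on $(-\pi/2,\pi/2)$; adaptive
quadrature (`stats::integrate`, relative tolerance $10^{-10}$) is applied on
the two subintervals split at the likelihood mode
$\theta_0=\arctan(t/(r\sqrt n))$. The noncentral-t density is taken in log
space; at extreme noncentralities where R's `dt` underflows (and warns), the
integrand is clamped to zero. A brute-force trapezoid rule on
$\delta\in[-15,15]$ with $2\times10^5$ nodes serves as the independent
oracle in the tests (agreement to $10^{-5}$ relative).

`posterior_delta()` returns the normalized posterior as a pair of
quadrature-backed queries (`ordinate`, `mass_below`); `bf_plus_minus()` is
the posterior odds of a positive versus negative effect, asymptotically
$(1-p)/p$ for the one-sided p value (`directional_p_relation()`); and
`savage_dickey_bf10()` recovers the two-sided Bayes factor as the
prior-to-posterior ordinate ratio at $\delta=0$ (prior ordinate
$1/(\pi r)\approx 0.45$). Holding the posterior mass below zero fixed at
$0.0204$ while n grows through 20, 82, 332 keeps the directional odds at
$\approx 48$ while BF10 falls $2 \to 1 \to 1/2$ (`figure1_panels()`): two
coherent Bayesian questions, opposite verdicts.

## The peri-null version: no point mass required

Replace the point null by a narrow normal prior
$\delta\sim\mathcal{N}(0,g_0)$ and keep a wider
$\delta\sim\mathcal{N}(0,g_1)$, $g_0<g_1$, for a z test with known unit
variance. Both marginals are then normal, $z\sim\mathcal{N}(0,1+ng_k)$, and

$$\mathrm{BF}_{\widetilde{0}1}(z,n)
 = \sqrt{\frac{1+ng_1}{1+ng_0}}
 \exp\!\Big(\frac{(g_0-g_1)\,n z^2}{2(1+ng_0)(1+ng_1)}\Big).$$

At a fixed-$\alpha$ statistic the factor starts at 1 (n = 0), dips below 1
at small n whenever $z>1$ (the derivative at the origin is
$\tfrac12(g_1-g_0)(1-z^2)$), and then climbs monotonically to the bound
$\sqrt{g_1/g_0}$ (`perinull_limit()`). The evidence for the null is bounded
— the one real change from the point-mass case — but still in the null's
favour for every $\alpha$, so the paradox does not hinge on the point mass.
Two statistic conventions are exposed because the published curves use the
one-sided quantile $z=\Phi^{-1}(1-\alpha)$ while describing a two-sided
test: `z_convention = "paper"` (default, reproduces the curves) and
`"two_sided"` ($\Phi^{-1}(1-\alpha/2)$). The default $g_1 = 1$ used for
curve regeneration is a choice (the sources print only $g_0$); it is an
argument everywhere.

## The frequentist version

A tester who fixes $\alpha$ and minimizes $\beta$ keeps a constant
threshold. A tester who minimizes the *weighted total* $\lambda\alpha+\beta$
— with effect frequencies in the world matching the prior, here
$\delta\sim\mathcal{N}(0,g)$ so the marginal of $z$ under $\mathcal{M}_1$ is
$\mathcal{N}(0,1+ng)$ — finds the first-order condition
$\lambda\varphi(c)=\varphi_{1+ng}(c)$, which for $\lambda=1$ is exactly
$\mathrm{BF}_{01}(c)=1$: the error-minimizing line is the even-odds line,
and it moves outward with n. `weighted_error_threshold()` implements this
by a coarse grid scan (the objective is flat far outside the informative
region, where golden-section search alone can stall), local `optimize()`,
and a final polish on the first-order condition; the tests verify agreement
with the $K=1$ root to $10^{-6}$ across an (n, g) grid. The normal-g world
model is the natural modern reading of the original uniform-calibration
argument; it is a design choice, not the only possible one.

## Discrete demonstrations

`binom_two_sided_p()` doubles the smaller exact binomial tail (capped at 1);
at $p_0=1/2$, the only case the demonstrations need, this coincides with
the "at least as extreme on either side" convention, and the doubling rule
is fixed and documented for $p_0\neq\tfrac12$. The coin construction
(`simplissimus_construct()`) resolves an under-specified search rule as:
the smallest n whose rounded success count $k=\mathrm{round}(n(0.5+
\epsilon/7))$ attains a two-sided tail $\le$ the target — the published
endpoint (16,700 tosses, 8,517 heads, p just below 0.01) satisfies this
rule, and the attained p is always reported so the endpoint can be checked
independently of the search convention. The urn demonstration
(`bag_best_alternative()`) enumerates all compositions including the pure
ones; with a mixed sample the pure compositions carry zero likelihood, so
for the ten-ball urn the enumeration matches the interior-composition
reading, while the two-ball urn correctly yields infinite support for the
even split.

## What the synthetic generator does and does not emulate

`simulate_one_sample()` draws i.i.d. $\mathcal{N}(\delta, 1)$ observations
and computes the one-sample t statistic — precisely the sampling model the
Cauchy-prior t test assumes. It emulates nothing else: no heavy tails, no
dependence, no optional stopping. A green stochastic test therefore
establishes internal consistency (the Bayes factor concentrates on the true
hypothesis as n grows under its own model: median BF01 rising with n under
$\delta=0$, BF10 > 10 almost always at $n=100$ under $\delta=1$), not
robustness to model violation. The generator restores the caller's RNG
state, so seeded test replication cannot leak into other code.

## Numerical choices, in one place

* Every Bayes factor is computed and stored in log space; linear `bf01`,
  `bf10` are derived and may round to 0 or `Inf` (permitted on the linear
  scale only). `generic_bf01()` keeps a finite `log_bf01` up to
  $|a/s| = 300$ and beyond.
* Closed forms are preferred to root-finders (`critical_ratio`,
  `two_prop_critical_diff`); where a numeric root is needed, `uniroot` with
  tolerance $10^{-10}$ or better.
* Quadrature tolerances: $10^{-10}$ relative for the Cauchy-prior marginal
  and posterior queries, one order tighter than the $10^{-8}$ accuracy the
  tests assert.
* p-to-statistic conversion is two-sided (upper $p/2$ quantile) in
  `calibrate_p_to_bf()`; the peri-null module's "paper" convention is the
  deliberate, flagged exception.
* Display rounding in the table helpers (2-3 decimals) never replaces the
  raw double-precision values, which sit alongside in the same data frame.

## Known limitations

* The approximate forms are large-sample results; the package reports them
  faithfully at any n but warns only where the historical sources did
  (t test with n < 4).
* The uniform-departure constant c and the historical Table of that test
  cannot be reconstructed from the available sources; only monotonicity is
  guaranteed.
* `table2()`'s n = 5 entry is 1.0760 by the stated formula; the historical
  cell prints 1.07 (a truncation). The package reports the formula value.
* Peri-null machinery covers the z case only; no t or binomial peri-null
  variants are provided.
* No posterior intervals, multi-degree-of-freedom tests, two-sample or
  paired designs, or sequential analyses.
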