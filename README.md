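# jlparadox

Bayes factors whose evidence for a point-null hypothesis scales with
&radic;n — and the constructions that turn that scaling into the
Jeffreys–Lindley paradox.

## The problem

A two-sided significance test rejects a null hypothesis H₀ whenever the
estimate exceeds a *constant* multiple of its standard error (1.96 at
α = 0.05). A Bayes factor compares how well H₀ and a composite alternative
H₁ *predicted* the data, and it does not draw the line at a constant
multiple. For the recurring case of a point estimate `a` with standard error
`s` and a prior that spreads the new parameter over a range `m`, the
approximate Bayes factor in favour of the null is

    BF01 = m / (√(2π) s) · exp(−a² / (2s²)),

and since `s ∝ 1/√n` the leading ("outside") factor grows like √n. The
break-even ratio `a/s` solving BF01 = 1 is therefore `√log(An)` for a
test-specific constant `A`: it grows with n. Hold a p value fixed at any
α while n grows and the two procedures must eventually disagree — the data
are "significant" yet the Bayes factor supports H₀. That is the
Jeffreys–Lindley paradox. The package makes every piece of this computable:

* **Generic forms and calibration** — `generic_bf01()`, `sqrt_An_bf01()`,
  `critical_ratio()`, the classical calibration tables `table1()`,
  `table2()`, `table3()`, and `calibrate_p_to_bf()`.
* **Concrete tests** — the exact and asymptotic two-proportion Bayes factors
  (`two_prop_bf01_exact()`, `two_prop_bf01_asymptotic()`,
  `two_prop_critical_diff()`), the 1938 one-sample t-test Bayes factor
  `K = √(2n/π)(1 + t²/(n−1))^{−(n−3)/2}` (`ttest_bf01_1938()`), and the
  uniform-departure test (`uniform_departure_bf01()`).
* **The default Cauchy-prior t test** — `bf10_cauchy()` integrates the
  noncentral-t likelihood against a zero-centred Cauchy prior (scale 1/√2)
  on the effect size δ = μ/σ; `posterior_delta()` exposes the posterior,
  `bf_plus_minus()` the directional Bayes factor, `savage_dickey_bf10()` the
  prior/posterior ordinate ratio at δ = 0.
* **The peri-null version** — `perinull_bf01()` shows the paradox survives
  without any point mass: with nested normal priors (variances g₀ < g₁) the
  Bayes factor at a fixed-α statistic climbs to the bound
  `√(g₁/g₀)` (`perinull_limit()`, `perinull_curve()`).
* **Paradox constructions** — `paradox_construct()` finds the smallest n at
  which an exactly-significant result carries a prescribed amount of
  evidence *for* the null; `simplissimus_construct()` and
  `bag_best_alternative()` are the classical coin and urn demonstrations;
  `weighted_error_threshold()` shows the frequentist face of the paradox
  (minimizing λα + β lands on the BF01 = 1 threshold);
  `binom_two_sided_p()` gives exact binomial tails and
  `simulate_one_sample()` generates synthetic one-sample data.

## Worked example

The same evidence for direction, shrinking evidence for existence. Three
samples are tuned so a Bayesian directional test is equally confident the
effect is positive — while the Bayes factor for the effect's *existence*
slides from "for" to "against":

```r
library(jlparadox)
figure1_panels()
#>       t   n mass_below_0 bf_plus_minus      bf10
#> 1 2.321  20   0.02041673      47.97945 2.0000909
#> 2 2.113  82   0.02041455      47.98466 0.9995957
#> 3 2.062 332   0.02043029      47.94694 0.4997691
```

Each row leaves about 2% posterior mass on a negative effect (directional
odds ≈ 48), yet BF10 falls from 2 to 1/2 as n rises from 20 to 332. The
constructive version: how many observations make a p = 0.05 result worth
10-to-1 odds *for* the null under a unit-information normal prior?

```r
paradox_construct(0.05, normal_prior(1), 10)
#> $n
#> [1] 4655
#> $statistic
#> [1] 1.959964
#> $bf01
#> [1] 10.00054
```

At n = 4655 a z of exactly 1.96 — rejected by every fixed-α tester — is
ten times better predicted by the null.

## Acceptance script

`scripts/acceptance.R` recomputes the package's quantitative anchors from
scratch (the two-proportion table entry at equal splits, the least-squares
critical ratios at n = 100 and 100,000, the 1938 t-test Bayes factors at the
5% points for n = 5 and 10, and the Cauchy-prior directional and two-sided
Bayes factors at the demonstration panels) and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette (`vignettes/jeffreys-lindley.Rmd`) documents the
models, the numerical choices (log-space evaluation, the tan-substitution
quadrature for the Cauchy-prior t test), the conventions adopted where the
historical sources are ambiguous, and known limitations.
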