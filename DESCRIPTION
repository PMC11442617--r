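Package: jlparadox
Title: Bayes Factors and the Jeffreys-Lindley Paradox
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the classical approximate Bayes factors of Harold
    Jeffreys (generic sqrt(n) forms, two-proportion exact and asymptotic
    tests, the 1938 one-sample t test, uniform-departure tests) together
    with their critical-ratio calibration tables, the default Cauchy-prior
    one-sample t Bayes factor with Savage-Dickey and directional variants,
    the peri-null normal-prior Bayes factor and its sample-size limit, and
    constructions that exhibit the Jeffreys-Lindley paradox: the sample-size
    regime where a fixed-alpha significance test rejects a null hypothesis
    that the Bayes factor simultaneously supports. Includes exact binomial
    tail tests, weighted Type I/II error thresholds, and a synthetic
    one-sample data generator for end-to-end checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
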