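Package: regbf
Title: Default Bayes Factors for Equality and Order Constraints on Regression Coefficients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests multiple hypotheses with equality and order (inequality)
    constraints on the coefficients of a linear regression model using
    prior-adjusted default (fractional) Bayes factors. The implicit prior is
    built from a minimal fraction b = (k+1)/n of the data and relocated to the
    boundary of the constrained space, giving analytic Savage-Dickey density
    ratios and multivariate Student-t polytope probabilities. Provides
    confirmatory tests against an automatically added complement hypothesis,
    exploratory zero/positive/negative sweeps over all coefficients, posterior
    hypothesis probabilities, fit/complexity decompositions, and Monte Carlo
    error intervals, together with deterministic synthetic-data generators for
    regression fixtures with exactly prescribed least-squares statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mvtnorm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
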