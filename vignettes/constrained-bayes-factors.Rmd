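---
title: "Default Bayes factors for equality and order constraints on regression coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Default Bayes factors for equality and order constraints on regression coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regbf)
```

## The model and the hypotheses

`regbf` works with the normal linear regression model

$$\mathbf{y} = \mathbf{X}\boldsymbol\beta + N(\mathbf{0}, \sigma^2 \mathbf{I}_n),$$

with $n$ observations and $k$ design columns (usually an intercept plus
predictors), and evaluates hypotheses of the form

$$H_t : \mathbf{R}_E\boldsymbol\beta = \mathbf{r}_E
\;\;\&\;\; \mathbf{R}_I\boldsymbol\beta > \mathbf{r}_I$$

against the unconstrained alternative $H_u$ and against each other.
Hypotheses are written in a small constraint language
(`"b1 > b2 > b3 > 0"`, `"b1 = b2 = b3 > 0"`, groups such as
`"a > (b, c) = 0"`, differences `"b1 - b2 > 0.2"`, and `&` to conjoin
fragments). Chains bind adjacent pairs only, `<` is normalised to `>`, and
every parsed hypothesis is checked for feasibility — a point satisfying the
equalities and *strictly* satisfying the inequalities must exist, found by
solving the equalities in minimum-norm form and then minimising squared hinge
violations at a positive margin (a small convex program) over the null space.

## The default Bayes factor

The testing criterion is a fractional Bayes factor whose implicit prior is
*relocated to the boundary of the constrained space*. Two ingredients matter:

1. **Minimal fraction.** The model has $k+1$ free parameters, so the smallest
   data fraction that yields a proper implicit prior is $b = (k+1)/n$. The
   fraction-$b$ posterior with a reference prior then has $bn - k = 1$ degree
   of freedom: the implicit prior for $\boldsymbol\beta$ is the heavy-tailed
   multivariate Cauchy $t(\cdot,\; s^2 (\mathbf{X}'\mathbf{X})^{-1},\; 1)$,
   where $s^2$ is the residual *sum of squares* (never divided by $n-k$).
2. **Relocation.** The prior is centred on the boundary of the constrained
   space (the null value for equalities, the constraint boundary for
   inequalities). Centring at the boundary makes the prior probability of a
   one-sided constraint exactly $1/2$ — so "positive effect" and "negative
   effect" count as equally complex — and, for two order constraints on
   orthogonal predictors, exactly $1/4$.

With $\hat{\boldsymbol\beta}$ the least-squares estimate, the fit components
come from the full-data posterior
$t(\hat{\boldsymbol\beta},\, s^2(\mathbf{X}'\mathbf{X})^{-1}/(n-k),\, n-k)$
and the complexity components from the relocated prior above. Equality-only
hypotheses give a Savage–Dickey density ratio (posterior over prior density
at $\mathbf{r}_E$); order-only hypotheses give a ratio of polytope
probabilities; mixed hypotheses multiply an equality ratio by a ratio of
*conditional* probabilities after the reparameterization
$\boldsymbol\xi = \mathbf{T}\boldsymbol\beta$, with
$\mathbf{T} = (\mathbf{R}_E', \mathbf{D}')'$ and $\mathbf{D}$ a deterministic
full-rank row selection from the projector
$\mathbf{I} - \mathbf{R}_E'(\mathbf{R}_E\mathbf{R}_E')^{-1}\mathbf{R}_E$
(pivots taken in row order; the Bayes factors are invariant to any valid
selection, and the package tests this invariance rather than assuming it).

One subtlety deserves a note. In the conditional complexity term the
fraction-$b$ prior is conditioned at its own centre
($\boldsymbol\xi_E = \hat{\boldsymbol\xi}_E$, conditional location
$\hat{\boldsymbol\xi}_I$, scale $\mathbf{S}_I^0 = \tfrac{s^2}{1+q_E}\times$
Schur complement, df 1) and evaluated against the threshold
$\mathbf{r}^*_I = \tilde{\mathbf{R}}_I\hat{\boldsymbol\xi}_I$. Because the
threshold sits at the centre of that conditional distribution, a single
surviving inequality always has conditional prior probability exactly 0.500,
irrespective of the data — which is also the behaviour the published
computation tables show. An equivalent formulation shifts the centre to the
boundary $\tilde{\mathbf{r}}_I$ instead; the probability is identical.

Posterior hypothesis probabilities are the normalised products
$B_{tu}\Pr(H_t)$; prior hypothesis probabilities are equal by default. A
complement hypothesis is appended automatically in confirmatory mode unless
the stated hypotheses already exhaust the space (its complexity would fall
below $10^{-10}$). Its components are $1-\sum f^I$ and $1-\sum c^I$ over the
*equality-free* hypotheses (equality-constrained ones occupy measure-zero
sets); this requires the order hypotheses to be pairwise disjoint, which is
verified by a seeded Monte Carlo intersection check, and overlapping
formulations are rejected with an error rather than approximated.

## Numerical choices

* **Polytope probabilities.** When the (transformed) constraint matrix has
  full row rank, $\boldsymbol\eta = \mathbf{R}\boldsymbol\xi$ is again
  Student-t and the rectangle probability is computed deterministically:
  exactly via `pt()` in one dimension, otherwise via `mvtnorm::pmvt`
  (Genz–Bretz, absolute tolerance $10^{-8}$, fixed internal quasi-random
  stream, caller RNG state untouched). These values are treated as analytic
  with zero standard error. Rank-deficient systems — e.g. the redundant rows
  that group expansion under equalities produces, which are deliberately kept
  rather than simplified away — use the proportion of `mcrep` seeded draws
  from the unconstrained t (default $10^6$), with binomial standard error
  $\sqrt{p(1-p)/\mathrm{mcrep}}$. Fit and complexity estimates use
  independent streams derived from the user seed.
* **Monte Carlo intervals.** The published output format prints 90%
  credibility intervals for numerically estimated Bayes factors without
  specifying their construction; here the binomial errors are propagated on
  the log scale, $\mathrm{var}(\log B) \approx (se_f/f)^2 + (se_c/c)^2$, with
  normal quantiles. A repeated-seed study in the test suite confirms about
  90% coverage of the analytic value.
* **Generalized inverses** are Moore–Penrose via SVD with cutoff
  $\max(\text{dim})\cdot\varepsilon\cdot\sigma_{\max}$; prior centres for
  rank-deficient stacked constraints use the minimum-norm solution.
* **Degenerate inputs.** Perfect fits ($s^2 = 0$), rank-deficient designs and
  $n \le k$ are rejected at model-fitting time; a saturated equality system
  ($q_E = k$) skips the transformation and uses the density ratio alone;
  an estimated complexity of exactly zero raises an error advising a larger
  `mcrep` instead of returning an infinite Bayes factor.
* **Rounding.** Printed values are rounded to three decimals; full precision
  is retained internally and in the JSON report.

## The synthetic-data generators

Two generators back the tests and examples. `sim_regression()` draws
predictors from a zero-mean multivariate normal with a requested correlation
matrix and adds normal noise — the standard idealisation of a small
observational regression study. `sim_exact_mle()` constructs a dataset whose
least-squares statistics $(\hat{\boldsymbol\beta}, s^2,
\mathbf{X}'\mathbf{X}, n)$ equal prescribed targets *exactly* (Cholesky
factor padded with zero rows, a Householder rotation to make the first column
a column of ones, and a residual built in the orthogonal complement with
prescribed norm). Because the Bayes factors depend on the data only through
these statistics, such fixtures make analytic targets seed-independent; it is
also how the package stands in for worked examples whose original simulated
datasets are not available — their printed fit/complexity values are treated
as assembly-level checks, not end-to-end reproduction targets, a limitation
stated openly.

What the generators do *not* emulate: non-normal errors, heteroscedasticity,
discrete or skewed predictors, measurement error, and missingness mechanisms
beyond listwise deletion. Passing tests therefore certify the probability
machinery and its calibration under the model's own assumptions, not
robustness of the method on messy real data.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mcrep` | $10^6$ draws | Monte Carlo size for rank-deficient constraint systems; standard error of each probability $\approx 5\times10^{-4}$ at the default |
| `seed` | none | makes all Monte Carlo steps reproducible |
| `priorprob` | `"equal"` | prior hypothesis probabilities, including the complement when added |
| `standardize` | `FALSE` | centre/scale all used columns so coefficients are comparable across predictors (recommended when constraints compare different variables) |

The fraction $b = (k+1)/n$ is part of the method's definition, not a tuning
knob, and is not exposed.

## Problem sizes used in the checks

The test suite runs entirely on synthetic data built in code: hand-checkable
fits with $n \le 5$, fixtures with $n$ between 25 and 120 and up to five
predictors, Monte Carlo comparisons at $10^4$–$10^5$ draws, and an evidence-
accumulation study with true effects $(0.6, 0.4, 0.2)$, unit noise and 50
replications at $n \in \{30, 100, 300\}$ — the median posterior probability
of the true ordering is non-decreasing in $n$ and exceeds 0.9 at $n = 300$.
A quadrature oracle (adaptive integration of the fractional marginal
likelihoods over $(\beta, \log\sigma^2)$, with the relocated fraction-$b$
prior) independently reproduces the analytic null-hypothesis Bayes factor to
a relative $10^{-3}$ for single-coefficient models.

## Known limitations

* Constraints are linear with unit-weight differences of named coefficients;
  arbitrary linear combinations (`2*b1 + b2 > 0`) and interval hypotheses
  beyond chain form are not supported.
* Complement construction requires disjoint order hypotheses; unions of
  overlapping regions are not estimated.
* Ordinary least squares only: no generalized linear models, weighted fits
  or robust estimators.
* Default Bayes factors use a data fraction for prior construction, so
  evidence cannot be updated sequentially by Bayes' theorem; recompute on the
  combined data instead.
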