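# Independent oracles. These deliberately avoid the package's own code paths:
# quadrature on likelihood kernels and closed-form orthant probabilities.

# Closed form for Pr(X1 > 0, X2 > 0) under a centred elliptical distribution
# with correlation rho (holds for the multivariate t at any df).
orthant2_prob <- function(rho) 0.25 + asin(rho) / (2 * pi)

# Adjusted fractional marginal likelihood oracle for k = 1 (no intercept):
# B_0u for H0: beta = 0 computed as (m1_0 / mb_0*) / (m1_u / mb_u*), where
# m1_t is the full-data marginal likelihood under H_t (reference prior
# 1/sigma^2, flat on beta) and mb_t* the fraction-b marginal with the implicit
# prior relocated to the boundary (under H0 the relocated fractional
# likelihood is evaluated at beta_hat). All four integrals are evaluated by
# adaptive quadrature over (beta, log sigma^2).
oracle_bf_null_k1 <- function(beta_hat, A, s2, n) {
  b <- 2 / n
  loglik <- function(beta, s2v, a = 1)
    -a * n / 2 * log(2 * pi * s2v) - a * (s2 + A * (beta - beta_hat)^2) / (2 * s2v)
  phi0 <- log(s2 / n)
  logint2d <- function(f, a) {
    C <- f(beta_hat, exp(phi0))
    inner <- function(phi) sapply(phi, function(p) {
      bs <- sqrt(exp(p) / (a * A))
      integrate(function(bb) exp(pmin(f(bb, exp(p)) + p - C, 700)),
                beta_hat - 15 * bs, beta_hat + 15 * bs, rel.tol = 1e-11)$value
    })
    log(integrate(inner, phi0 - 25, phi0 + 45, rel.tol = 1e-9,
                  subdivisions = 800L)$value) + C
  }
  logint1d <- function(f) {
    C <- f(exp(phi0))
    log(integrate(function(phi) sapply(phi, function(p)
      exp(pmin(f(exp(p)) + p - C, 700))),
      phi0 - 25, phi0 + 45, rel.tol = 1e-10, subdivisions = 800L)$value) + C
  }
  lm1_u  <- logint2d(function(bb, sv) loglik(bb, sv) - log(sv), 1)
  lm1_0  <- logint1d(function(sv) loglik(0, sv) - log(sv))
  lmb_u  <- logint2d(function(bb, sv) loglik(bb, sv, b) - log(sv), b)
  lmb_0r <- logint1d(function(sv) loglik(beta_hat, sv, b) - log(sv))
  exp((lm1_0 - lmb_0r) - (lm1_u - lmb_u))
}

# Brute-force conditional mean/scale of a multivariate t partitioned as
# (xi_E, xi_I) given xi_E = value, from the standard conditional-t formulas.
cond_t_moments <- function(loc, S, df, idxE, valE) {
  idxI <- setdiff(seq_along(loc), idxE)
  SEE <- S[idxE, idxE, drop = FALSE]
  SIE <- S[idxI, idxE, drop = FALSE]
  SII <- S[idxI, idxI, drop = FALSE]
  dev <- valE - loc[idxE]
  mu <- loc[idxI] + drop(SIE %*% solve(SEE, dev))
  d1 <- drop(t(dev) %*% solve(SEE, dev))
  Schur <- SII - SIE %*% solve(SEE, t(SIE))
  list(mu = mu, scale = (df + d1) / (df + length(idxE)) * Schur)
}
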