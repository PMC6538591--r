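# Shared fixtures, generated in code.

# Intercept-only fit with beta_hat = 0, s2 = 2, X'X = 3, n = 3: every equality
# Bayes factor quantity is hand-computable.
fit_intercept_only <- function() {
  linreg_stats_from_summary(beta_hat = 0, xtx = matrix(3), s2 = 2, n = 3,
                            names = "(Intercept)")
}

# Two exactly orthogonal centred predictors plus intercept.
fit_orthogonal2 <- function(n = 40, beta = c(0, 0.5, 0.2), s2 = n - 3) {
  d <- sim_exact_mle(beta, s2 = s2, xtx = diag(c(n, n, n)), n = n,
                     intercept = TRUE, seed = 11)
  linreg_stats(y ~ x1 + x2, d)
}

# Generic 3-predictor fit used by parser/transform/reporting tests.
fit_three_pred <- function(n = 60, beta = c(0.6, 0.3, 0), seed = 7) {
  d <- sim_regression(n, beta = beta, seed = seed)
  linreg_stats(y ~ x1 + x2 + x3, d)
}

# Random feasible constraint system on k coefficients (for property tests).
random_order_system <- function(k, q, seed) {
  set.seed(seed)
  repeat {
    R <- matrix(sample(-1:1, q * k, replace = TRUE), q, k)
    R <- R[rowSums(abs(R)) > 0, , drop = FALSE]
    if (nrow(R) == q && regbf:::mat_rank(R) == q) break
  }
  r <- round(rnorm(q, sd = 0.3), 2)
  R <- R * 1.0
  sys <- regbf:::new_constraint_system(NULL, NULL, R, r, "H1", "random",
                                       paste0("b", seq_len(k)))
  sys
}
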