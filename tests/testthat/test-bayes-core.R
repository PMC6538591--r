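test_that("equality Bayes factor matches hand-computed densities", {
  # beta_hat = 0, s2 = 2, X'X = 3, n = 3, H: beta = 0
  fit <- fit_intercept_only()
  sys <- parse_hypotheses("(Intercept) = 0", fit$coef_names)[[1]]
  term <- bf_equality(fit, sys)
  # posterior: t(0, s2 (n-k)^-1 / xtx, n-k) = t(0, 1/3, 2) at 0
  expect_equal(term$fE, sqrt(1.5) / 2, tolerance = 1e-12)
  # prior: Cauchy scale sqrt(2/3) at its centre
  expect_equal(term$cE, sqrt(1.5) / pi, tolerance = 1e-12)
  expect_equal(term$B, pi / 2, tolerance = 1e-12)
})

test_that("a null at the MLE maximises the equality Bayes factor over r_E", {
  d <- sim_regression(25, beta = c(0.4, 0), seed = 3)
  fit <- linreg_stats(y ~ x1 + x2, d)
  at_mle <- sprintf("x1 = %.10f", fit$beta_hat[["x1"]])
  B0 <- bf_test(fit, at_mle)$b_u[["H1"]]
  for (off in c(-0.5, -0.1, 0.1, 0.5)) {
    Bo <- bf_test(fit, sprintf("x1 = %.10f", fit$beta_hat[["x1"]] + off))
    expect_lt(Bo$b_u[["H1"]], B0)
  }
})

test_that("order Bayes factor is one when the estimate sits on the boundary", {
  # beta_hat exactly 0 for the tested coefficient: fit = complexity = 1/2
  d <- sim_exact_mle(c(0.3, 0), s2 = 20, xtx = diag(c(25, 18)), n = 25,
                     intercept = FALSE, seed = 2)
  fit <- linreg_stats(y ~ x1 + x2 - 1, d)
  sys <- parse_hypotheses("x2 > 0", fit$coef_names)[[1]]
  term <- bf_order(fit, sys)
  expect_equal(term$fI$value, 0.5, tolerance = 1e-10)
  expect_equal(term$cI$value, 0.5, tolerance = 1e-10)
  expect_equal(term$B, 1, tolerance = 1e-9)
})

test_that("joint positivity of orthogonalized predictors has prior probability 1/4", {
  fit <- fit_orthogonal2()
  sys <- parse_hypotheses("(x1, x2) > 0", fit$coef_names)[[1]]
  term <- bf_order(fit, sys)
  expect_equal(term$cI$value, 0.25, tolerance = 1e-7)
  # the prior probability does not depend on y: different targets, same c
  fit2 <- fit_orthogonal2(beta = c(1, -2, 3), s2 = 80)
  term2 <- bf_order(fit2, parse_hypotheses("(x1, x2) > 0", fit2$coef_names)[[1]])
  expect_equal(term2$cI$value, 0.25, tolerance = 1e-7)
})

test_that("conditional moments match brute-force conditional-t formulas", {
  fit <- fit_three_pred()
  sys <- parse_hypotheses("x1 = 0.15 & x2 > 0", fit$coef_names)[[1]]
  ts <- transform_system(sys)
  cm <- conditional_moments(fit, sys, ts)
  nu <- fit$n - fit$k
  # joint posterior of xi = T beta: t(T beta_hat, s2/(n-k) T (X'X)^-1 T', n-k)
  S_xi <- fit$s2 / nu * ts$T %*% solve(fit$xtx) %*% t(ts$T)
  oracle <- cond_t_moments(drop(ts$T %*% fit$beta_hat), S_xi, nu,
                           idxE = 1, valE = sys$r_E)
  expect_equal(cm$mu_I_N, oracle$mu, tolerance = 1e-9)
  expect_equal(cm$S_I_N, oracle$scale, tolerance = 1e-9)
  # conditioning at the fitted value removes the inflation factor
  sys0 <- sys
  sys0$r_E <- drop(sys$R_E %*% fit$beta_hat)
  cm0 <- conditional_moments(fit, sys0, transform_system(sys0))
  Schur <- cm0$S_I_0 * (1 + 1) / fit$s2  # unscale the prior Schur complement
  expect_equal(cm0$S_I_N, fit$s2 / (nu + 1) * Schur, tolerance = 1e-10)
})

test_that("prior conditional scale is the Schur complement for a diagonal X'X", {
  fit <- linreg_stats_from_summary(c(0.5, -0.2), diag(c(4, 9)), s2 = 6, n = 12,
                                   names = c("b1", "b2"))
  sys <- parse_hypotheses("b1 = 0 & b2 > 0", fit$coef_names)[[1]]
  ts <- transform_system(sys)
  cm <- conditional_moments(fit, sys, ts)
  # D = [0, 1]; Schur complement of a diagonal matrix is just 1/xtx[2,2]
  expect_equal(cm$S_I_0, matrix(6 / (1 + 1) / 9), tolerance = 1e-12)
})

test_that("a single surviving conditional inequality has prior probability exactly 0.5", {
  for (fit in list(fit_three_pred(), fit_orthogonal2())) {
    sys <- parse_hypotheses("x1 > x2 = 0", fit$coef_names)[[1]]
    term <- bf_combined(fit, sys)
    expect_equal(term$cI$value, 0.5, tolerance = 1e-12)
    expect_equal(term$cI$method, "analytic")
  }
})

test_that("combined reduces to the equality Bayes factor when no inequality survives", {
  fit <- fit_three_pred()
  eq <- bf_equality(fit, parse_hypotheses("x1 = x2", fit$coef_names)[[1]])
  comb <- bf_combined(fit, parse_hypotheses("x1 = x2", fit$coef_names)[[1]])
  expect_equal(comb$B, eq$B, tolerance = 1e-12)
  # saturated equality system: all coefficients pinned
  sat <- parse_hypotheses("(Intercept) = 0 & x1 = 0 & x2 = 0 & x3 = 0",
                          fit$coef_names)[[1]]
  expect_equal(nrow(sat$R_E), 4L)
  term <- bf_combined(fit, sat)
  expect_true(is.null(term$fI))
  expect_gt(term$B, 0)
})

test_that("complement components mirror the fit/complexity of the order hypotheses", {
  # assembly contract with the worked two-predictor components
  mk <- function(f, c) regbf:::new_bf_terms("H", "h",
    fI = regbf:::new_prob_estimate(f, 0, "analytic", 0L),
    cI = regbf:::new_prob_estimate(c, 0, "analytic", 0L))
  comp <- bf_complement(list(mk(0.546, 0.250)))
  expect_equal(comp$fI$value, 0.454, tolerance = 1e-12)
  expect_equal(comp$cI$value, 0.750, tolerance = 1e-12)
  expect_equal(comp$B, 0.454 / 0.750, tolerance = 1e-12)
  # exhaustive order hypotheses leave no room for a complement
  expect_null(bf_complement(list(mk(0.7, 0.5), mk(0.3, 0.5))))
  # with only measure-zero (equality) hypotheses the complement is everything
  expect_equal(bf_complement(list())$B, 1)
})

test_that("posterior probabilities reproduce the worked normalizations", {
  p <- posterior_probabilities(c(0.383, 2.183, 10.061, 0.606), "equal")
  expect_equal(round(p, 3), c(0.029, 0.165, 0.760, 0.046))
  p2 <- posterior_probabilities(c(58.265, 32.525, 0.036, 0.357), "equal")
  expect_equal(round(p2[1], 3), 0.639)
  expect_equal(posterior_probabilities(7.7), 1)
  expect_equal(sum(p), 1, tolerance = 1e-15)
  # non-equal priors reweight
  p3 <- posterior_probabilities(c(2, 1), c(1, 2))
  expect_equal(p3, c(0.5, 0.5))
  expect_error(posterior_probabilities(c(1, Inf)), "finite")
})

test_that("the Bayes factor matrix is transitive with unit diagonal", {
  B <- c(H1 = 0.383, H2 = 2.183, H3 = 10.061, Hc = 0.606)
  M <- bf_pairwise_matrix(B)
  expect_equal(M["H3", "H1"], 10.061 / 0.383, tolerance = 1e-12)
  expect_equal(diag(M), setNames(rep(1, 4), names(B)))
  for (t in 1:4) for (s in 1:4) for (r in 1:4)
    expect_equal(M[t, s] * M[s, r], M[t, r], tolerance = 1e-12)
})

test_that("interval width shrinks like one over the square root of mcrep", {
  fit <- fit_three_pred()
  sys <- parse_hypotheses("x1 > (x2, x3) = 0", fit$coef_names)[[1]]
  widths <- vapply(c(1e4, 1e5, 1e6), function(m) {
    term <- bf_combined(fit, sys, mcrep = m, seed = 42)
    ci <- bf_interval(term)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_equal(widths[1] / widths[2], sqrt(10), tolerance = 0.35)
  expect_equal(widths[2] / widths[3], sqrt(10), tolerance = 0.35)
  # analytic terms carry no interval
  expect_null(bf_interval(bf_equality(
    fit, parse_hypotheses("x1 = 0", fit$coef_names)[[1]])))
})

test_that("90% Monte Carlo intervals cover the analytic Bayes factor about 90% of the time", {
  fit <- fit_three_pred()
  sys_full <- parse_hypotheses("x1 > x2", fit$coef_names)[[1]]
  B_exact <- bf_order(fit, sys_full)$B
  # same region with a duplicated row so the estimator goes Monte Carlo
  sys_dup <- sys_full
  sys_dup$R_I <- rbind(sys_full$R_I, sys_full$R_I)
  sys_dup$r_I <- c(sys_full$r_I, sys_full$r_I)
  hits <- vapply(1:200, function(i) {
    term <- bf_order(fit, sys_dup, mcrep = 1e4, seed = 5000 + i)
    ci <- bf_interval(term)
    ci[["lower"]] <= B_exact && B_exact <= ci[["upper"]]
  }, logical(1))
  expect_gt(mean(hits), 0.84)
  expect_lt(mean(hits), 0.97)
})

test_that("all Bayes factors are invariant to rescaling y when thresholds are zero", {
  d <- sim_regression(40, beta = c(0.5, 0.2, -0.1), seed = 21)
  fit1 <- linreg_stats(y ~ x1 + x2 + x3, d)
  d2 <- d; d2$y <- 2 * d2$y
  fit2 <- linreg_stats(y ~ x1 + x2 + x3, d2)
  hyp <- "x1 > x2 > 0; x1 = x2; x1 > (x2, x3) = 0"
  r1 <- bf_test(fit1, hyp, seed = 8)
  r2 <- bf_test(fit2, hyp, seed = 8)
  expect_equal(r2$b_u, r1$b_u, tolerance = 1e-9)
})
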