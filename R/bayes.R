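# Assembly of fit/complexity components into default Bayes factors.
#
# Fit ("f") components come from the full-data posterior
#   beta | y ~ t(beta_hat, s2 (X'X)^-1 / (n-k), n-k),
# complexity ("c") components from the implicit fraction-b prior relocated to
# the boundary of the constrained space,
#   beta | y^b ~ t(boundary, s2 (X'X)^-1, 1),
# with b = (k+1)/n the minimal fraction for k coefficients plus one variance.

new_bf_terms <- function(label, source, fE = NULL, cE = NULL,
                         fI = NULL, cI = NULL) {
  ratio <- function(num, den) {
    if (is.null(num)) return(1)
    nv <- if (inherits(num, "prob_estimate")) num$value else num
    dv <- if (inherits(den, "prob_estimate")) den$value else den
    nv / dv
  }
  B <- ratio(fE, cE) * ratio(fI, cI)
  if (!is.finite(B))
    stop("nonfinite Bayes factor for hypothesis '", source,
         "' (complexity component numerically zero; increase mcrep)")
  structure(list(label = label, source = source, fE = fE, cE = cE,
                 fI = fI, cI = cI, B = B),
            class = "bf_terms")
}

uses_mc <- function(term) {
  any(vapply(list(term$fI, term$cI), function(p)
    inherits(p, "prob_estimate") && p$method == "monte_carlo", logical(1)))
}

#' Bayes factor for an equality-constrained hypothesis
#'
#' Savage-Dickey density ratio for `H: R_E beta = r_E` against the
#' unconstrained model: the full-data posterior t density at `r_E` (df `n-k`,
#' scale `s2 (n-k)^-1 R_E (X'X)^-1 R_E'`) over the relocated fraction-b prior
#' Cauchy density evaluated at its own centre (df 1, scale
#' `s2 R_E (X'X)^-1 R_E'`).
#'
#' @param fit a `"linreg_stats"` object.
#' @param sys a `"constraint_system"` with equality rows only.
#' @return A `"bf_terms"` object with components `fE`, `cE` and `B`.
#' @export
bf_equality <- function(fit, sys) {
  qE <- nrow(sys$R_E)
  if (qE < 1L || nrow(sys$R_I) > 0L)
    stop("bf_equality requires equality constraints only")
  XtXi <- solve(fit$xtx)
  G <- sys$R_E %*% XtXi %*% t(sys$R_E)
  G <- (G + t(G)) / 2
  if (!is_spd(G)) stop("R_E (X'X)^-1 R_E' is singular")
  nu <- fit$n - fit$k
  fE <- mvt_density(sys$r_E, drop(sys$R_E %*% fit$beta_hat),
                    fit$s2 / nu * G, nu)
  cE <- mvt_density(sys$r_E, sys$r_E, fit$s2 * G, 1)
  new_bf_terms(sys$label, sys$source, fE = fE, cE = cE)
}

#' Bayes factor for an order-constrained hypothesis
#'
#' For `H: R_I beta > r_I` the Bayes factor against the unconstrained model is
#' the ratio of the posterior probability of the constraints (under
#' `t(beta_hat, s2 (X'X)^-1/(n-k), n-k)`) to their prior probability under the
#' relocated fraction-b prior `t(R_I^- r_I, s2 (X'X)^-1, 1)` centred at the
#' minimum-norm boundary point. Monte Carlo standard errors are attached when
#' `R_I` is rank deficient.
#'
#' @param fit a `"linreg_stats"` object.
#' @param sys a `"constraint_system"` with inequality rows only.
#' @param mcrep Monte Carlo draws for rank-deficient constraint matrices.
#' @param seed optional integer seed (two independent streams are derived for
#'   the fit and complexity estimates).
#' @return A `"bf_terms"` object with components `fI`, `cI` and `B`.
#' @export
bf_order <- function(fit, sys, mcrep = 1e6, seed = NULL) {
  qI <- nrow(sys$R_I)
  if (qI < 1L || nrow(sys$R_E) > 0L)
    stop("bf_order requires inequality constraints only")
  XtXi <- solve(fit$xtx)
  nu <- fit$n - fit$k
  seeds <- derive_seeds(seed, 2L)
  fI <- mvt_polytope_prob(sys$R_I, sys$r_I, fit$beta_hat,
                          fit$s2 * XtXi / nu, nu, mcrep, seeds[1])
  center0 <- drop(pinv(sys$R_I) %*% sys$r_I)
  cI <- mvt_polytope_prob(sys$R_I, sys$r_I, center0,
                          fit$s2 * XtXi, 1, mcrep, seeds[2])
  if (cI$value <= 0)
    stop("prior probability of '", sys$source, "' estimated as zero; ",
         "increase mcrep")
  new_bf_terms(sys$label, sys$source, fI = fI, cI = cI)
}

#' Conditional Student-t moments for combined hypotheses
#'
#' Location and scale of the free directions `xi_I` conditional on the
#' equality constraints, for the full-data posterior and the fraction-b
#' prior:
#' \itemize{
#' \item `mu_I_N = D beta_hat + D (X'X)^-1 R_E' (R_E (X'X)^-1 R_E')^-1
#'   (r_E - R_E beta_hat)`, the conditional posterior mean;
#' \item `S_I_N`, the conditional posterior scale with its
#'   `(n - k + q_E)^-1` constant and quadratic-form inflation factor;
#' \item `S_I_0 = s2/(1+q_E)` times the Schur complement, the conditional
#'   prior scale.
#' }
#' Also returns `xi_I_hat = D beta_hat` and the prior-boundary threshold
#' `r_star_I = Rtilde_I xi_I_hat`.
#'
#' @param fit a `"linreg_stats"` object.
#' @param sys the original `"constraint_system"`.
#' @param tsys the matching `"transformed_system"`.
#' @return List with `mu_I_N`, `S_I_N`, `S_I_0`, `r_star_I`, `xi_I_hat`,
#'   `post_df = n - k` and `prior_df = 1`.
#' @export
conditional_moments <- function(fit, sys, tsys) {
  qE <- nrow(sys$R_E)
  if (qE < 1L || qE >= fit$k)
    stop("conditional moments require 1 <= q_E < k")
  XtXi <- solve(fit$xtx)
  D <- tsys$D
  RE <- sys$R_E
  G <- RE %*% XtXi %*% t(RE)
  G <- (G + t(G)) / 2
  if (!is_spd(G)) stop("singular conditioning block R_E (X'X)^-1 R_E'")
  W <- solve(G)
  resE <- drop(sys$r_E - RE %*% fit$beta_hat)
  muN <- drop(D %*% fit$beta_hat + D %*% XtXi %*% t(RE) %*% W %*% resE)
  Schur <- D %*% XtXi %*% t(D) -
    D %*% XtXi %*% t(RE) %*% W %*% RE %*% XtXi %*% t(D)
  Schur <- (Schur + t(Schur)) / 2
  infl <- 1 + drop(t(resE) %*% W %*% resE) / fit$s2
  nu <- fit$n - fit$k
  xi_hat <- drop(tsys$T %*% fit$beta_hat)
  xi_I_hat <- xi_hat[(qE + 1L):fit$k]
  list(mu_I_N = muN,
       S_I_N = infl * fit$s2 / (nu + qE) * Schur,
       S_I_0 = fit$s2 / (1 + qE) * Schur,
       r_star_I = drop(tsys$Rtilde_I %*% xi_I_hat),
       xi_I_hat = xi_I_hat,
       post_df = nu, prior_df = 1)
}

#' Bayes factor for a hypothesis with equality and order constraints
#'
#' Product of the Savage-Dickey equality ratio on `(R_E, r_E)` (as in
#' [bf_equality()]) and the conditional order ratio: the posterior probability
#' `Pr(Rtilde_I xi_I > rtilde_I | xi_E = r_E, y)` under
#' `t(mu_I_N, S_I_N, n-k)` over the prior probability
#' `Pr(Rtilde_I xi_I > r*_I | xi_E = xi_hat_E, y^b)` under the fraction-b
#' prior conditioned at its own centre, `t(xi_I_hat, S_I_0, 1)` — which makes
#' the prior conditional probability exactly 0.5 for a single surviving
#' inequality, irrespective of the data. When the equalities saturate the
#' model (`q_E = k`) the order part is void and the equality ratio alone is
#' returned.
#'
#' @inheritParams bf_order
#' @param tsys optional precomputed `"transformed_system"`.
#' @return A `"bf_terms"` object with components `fE`, `cE`, `fI`, `cI`, `B`.
#' @export
bf_combined <- function(fit, sys, tsys = NULL, mcrep = 1e6, seed = NULL) {
  qE <- nrow(sys$R_E); qI <- nrow(sys$R_I)
  if (qE < 1L) stop("bf_combined requires at least one equality constraint")
  eq_sys <- sys; eq_sys$R_I <- empty_rows(fit$k); eq_sys$r_I <- numeric()
  eq <- bf_equality(fit, eq_sys)
  if (qI == 0L || qE >= fit$k) return(eq)
  if (is.null(tsys)) tsys <- transform_system(sys)
  cm <- conditional_moments(fit, sys, tsys)
  seeds <- derive_seeds(seed, 2L)
  fI <- mvt_polytope_prob(tsys$Rtilde_I, tsys$rtilde_I, cm$mu_I_N, cm$S_I_N,
                          cm$post_df, mcrep, seeds[1])
  cI <- mvt_polytope_prob(tsys$Rtilde_I, cm$r_star_I, cm$xi_I_hat, cm$S_I_0,
                          cm$prior_df, mcrep, seeds[2])
  if (cI$value <= 0)
    stop("conditional prior probability of '", sys$source,
         "' estimated as zero; increase mcrep")
  new_bf_terms(sys$label, sys$source, fE = eq$fE, cE = eq$cE,
               fI = fI, cI = cI)
}

#' Bayes factor for the complement hypothesis
#'
#' The complement covers the parameter space excluded by all specified
#' hypotheses. Hypotheses containing equality constraints occupy measure-zero
#' sets and are ignored; for the remaining (pairwise disjoint) order
#' hypotheses the complement's fit and complexity are
#' `f_c = 1 - sum(f_I)` and `c_c = 1 - sum(c_I)`, so
#' `B_cu = (1 - sum f) / (1 - sum c)`. If the order hypotheses exhaust the
#' space (`c_c` below `1e-10`) no complement is needed and `NULL` is returned.
#' With no order hypotheses at all the complement is the unconstrained space
#' minus null sets, so `B_cu = 1`.
#'
#' @param order_terms list of `"bf_terms"` for the equality-free hypotheses.
#' @param label,source label and description for the complement.
#' @return A `"bf_terms"` object, or `NULL` when the specified hypotheses are
#'   exhaustive.
#' @export
bf_complement <- function(order_terms, label = "Hc", source = "complement") {
  if (length(order_terms) == 0L) {
    fI <- new_prob_estimate(1, 0, "analytic", 0L)
    cI <- new_prob_estimate(1, 0, "analytic", 0L)
    return(new_bf_terms(label, source, fI = fI, cI = cI))
  }
  fsum <- sum(vapply(order_terms, function(t) t$fI$value, numeric(1)))
  csum <- sum(vapply(order_terms, function(t) t$cI$value, numeric(1)))
  fse <- sqrt(sum(vapply(order_terms, function(t) t$fI$std_error^2, numeric(1))))
  cse <- sqrt(sum(vapply(order_terms, function(t) t$cI$std_error^2, numeric(1))))
  fc <- min(max(1 - fsum, 0), 1)
  cc <- min(max(1 - csum, 0), 1)
  if (cc < 1e-10) return(NULL)
  mc <- any(vapply(order_terms, uses_mc, logical(1)))
  method <- if (mc) "monte_carlo" else "analytic"
  draws <- max(vapply(order_terms, function(t)
    max(t$fI$draws_used, t$cI$draws_used), integer(1)))
  fI <- new_prob_estimate(fc, if (mc) fse else 0, method, draws)
  cI <- new_prob_estimate(cc, if (mc) cse else 0, method, draws)
  new_bf_terms(label, source, fI = fI, cI = cI)
}

#' Posterior hypothesis probabilities
#'
#' Normalized products of Bayes factors against the unconstrained model and
#' prior hypothesis probabilities:
#' `Pr(H_t | y) = B_tu Pr(H_t) / sum_s B_su Pr(H_s)`.
#'
#' @param bfs positive Bayes factors `B_tu`.
#' @param priors prior probabilities (`"equal"` or a nonnegative vector, not
#'   all zero; normalized internally).
#' @return Vector of posterior probabilities summing to one.
#' @export
posterior_probabilities <- function(bfs, priors = "equal") {
  bfs <- setNames(as.numeric(bfs), names(bfs))
  if (any(!is.finite(bfs)) || any(bfs < 0))
    stop("Bayes factors must be finite and nonnegative")
  if (identical(priors, "equal")) priors <- rep(1, length(bfs))
  priors <- as.numeric(priors)
  if (length(priors) != length(bfs))
    stop("priors must be 'equal' or match the number of hypotheses (",
         length(bfs), ")")
  if (any(priors < 0) || sum(priors) <= 0)
    stop("priors must be nonnegative and not all zero")
  w <- bfs * priors
  setNames(w / sum(w), names(bfs))
}

#' Bayes factor matrix via transitivity
#'
#' `M[t, s] = B_tu / B_su` is the Bayes factor of hypothesis `t` against
#' hypothesis `s`; the diagonal is one and `M[t,s] M[s,r] = M[t,r]` by
#' construction.
#'
#' @param bfs positive Bayes factors against the unconstrained hypothesis,
#'   optionally named.
#' @return Square matrix of pairwise Bayes factors.
#' @export
bf_pairwise_matrix <- function(bfs) {
  bfs <- as.numeric0named(bfs)
  if (any(bfs <= 0)) stop("all Bayes factors must be strictly positive")
  M <- outer(bfs, bfs, "/")
  dimnames(M) <- list(names(bfs), names(bfs))
  M
}

as.numeric0named <- function(x) setNames(as.numeric(x), names(x))

#' Monte Carlo credibility interval for a Bayes factor
#'
#' Propagates the binomial Monte Carlo errors of the fit and complexity
#' probabilities to the Bayes factor on the log scale
#' (`var(log B) = (se_f/f)^2 + (se_c/c)^2`, normal quantiles), clipped to the
#' positive reals. Fully analytic Bayes factors carry no numerical error and
#' return `NULL`.
#'
#' @param term a `"bf_terms"` object.
#' @param level interval level (default 0.90).
#' @return Numeric `c(lower, upper)`, or `NULL` for analytic terms.
#' @export
bf_interval <- function(term, level = 0.90) {
  comps <- Filter(function(p) inherits(p, "prob_estimate") &&
                    p$method == "monte_carlo", list(term$fI, term$cI))
  if (length(comps) == 0L) return(NULL)
  relvar <- sum(vapply(comps, function(p) (p$std_error / p$value)^2, numeric(1)))
  z <- qnorm(1 - (1 - level) / 2)
  s <- sqrt(relvar)
  c(lower = term$B * exp(-z * s), upper = term$B * exp(z * s))
}

# Deterministic sub-seed derivation (keeps every derived seed below 2^31).
derive_seeds <- function(seed, m) {
  if (is.null(seed)) return(sample.int(2147483646L, m))
  (as.integer(seed) + 1000003L * seq_len(m)) %% 2147483647L
}
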