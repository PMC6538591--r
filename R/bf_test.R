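#' Test equality/order-constrained hypotheses on regression coefficients
#'
#' Main entry point. Evaluates one or more hypotheses with equality and order
#' constraints on the coefficients of a linear regression model using
#' prior-adjusted default (fractional) Bayes factors, and returns Bayes
#' factors against the unconstrained model, pairwise Bayes factors, posterior
#' hypothesis probabilities, the fit/complexity decomposition and (when Monte
#' Carlo was needed) 90% credibility intervals for the numerical error.
#'
#' In confirmatory mode (`hyp` a semicolon-separated string of hypotheses) a
#' complement hypothesis covering the remaining parameter space is added
#' automatically unless the stated hypotheses already exhaust it. Multiple
#' equality-free order hypotheses must be disjoint; overlapping formulations
#' are rejected. With `hyp = "exploratory"` every coefficient (including the
#' intercept) is tested for a negative, zero or positive effect; the triple is
#' exhaustive so no complement is added.
#'
#' @param object a fitted `lm` object, a `"linreg_stats"` object, or a model
#'   formula (with `data` supplied).
#' @param hyp hypothesis string (see [parse_hypotheses()]) or
#'   `"exploratory"`.
#' @param data data frame; only used when `object` is a formula.
#' @param priorprob prior hypothesis probabilities: `"equal"` (default) or a
#'   nonnegative vector matching the number of reported hypotheses (including
#'   the complement when it is added).
#' @param mcrep Monte Carlo draws used when a constraint matrix is rank
#'   deficient (default `1e6`).
#' @param seed optional integer seed making any Monte Carlo step reproducible.
#' @param standardize standardize response and predictors before fitting
#'   (formula interface only).
#' @param ... passed between methods.
#' @return An object of class `"bf_test"`; see [print.bf_test()] and
#'   [summary.bf_test()]. Key elements: `post_prob`, `BF_matrix`,
#'   `BF_computation`, `BFu_CI`, `b_u` (Bayes factors against the
#'   unconstrained model).
#' @examples
#' d <- sim_regression(60, beta = c(0.6, 0.3, 0.0), seed = 7)
#' fit <- linreg_stats(y ~ x1 + x2 + x3, d)
#' bf_test(fit, "x1 > x2 > x3 > 0; x1 = x2 = x3 > 0", seed = 1)
#' bf_test(fit, "exploratory")
#' @export
bf_test <- function(object, ...) UseMethod("bf_test")

#' @rdname bf_test
#' @export
bf_test.formula <- function(object, data, hyp = "exploratory",
                            priorprob = "equal", mcrep = 1e6, seed = NULL,
                            standardize = FALSE, ...) {
  bf_test(linreg_stats(object, data, standardize = standardize), hyp = hyp,
          priorprob = priorprob, mcrep = mcrep, seed = seed, ...)
}

#' @rdname bf_test
#' @export
bf_test.lm <- function(object, hyp = "exploratory", priorprob = "equal",
                       mcrep = 1e6, seed = NULL, ...) {
  bf_test(as_linreg_stats(object), hyp = hyp, priorprob = priorprob,
          mcrep = mcrep, seed = seed, ...)
}

#' @rdname bf_test
#' @export
bf_test.linreg_stats <- function(object, hyp = "exploratory",
                                 priorprob = "equal", mcrep = 1e6,
                                 seed = NULL, ...) {
  if (!is.character(hyp) || length(hyp) != 1L || !nzchar(trimws(hyp)))
    stop("hyp must be a non-empty hypothesis string or \"exploratory\"")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (identical(trimws(hyp), "exploratory"))
    run_exploratory(object, mcrep, seed)
  else
    run_confirmatory(object, hyp, priorprob, mcrep, seed)
}

dispatch_bf <- function(fit, sys, mcrep, seed) {
  qE <- nrow(sys$R_E); qI <- nrow(sys$R_I)
  term <- tryCatch({
    if (qE > 0L && qI == 0L) bf_equality(fit, sys)
    else if (qE == 0L) bf_order(fit, sys, mcrep, seed)
    else bf_combined(fit, sys, mcrep = mcrep, seed = seed)
  }, error = function(e)
    stop("hypothesis '", sys$source, "': ", conditionMessage(e), call. = FALSE))
  term
}

# Seeded Monte Carlo check that equality-free order hypotheses are pairwise
# disjoint (the complement construction subtracts their probabilities).
check_disjoint <- function(fit, systems, seed, ndraw = 2e4) {
  if (length(systems) < 2L) return(invisible(TRUE))
  draws <- with_preserved_rng({
    mvtnorm::rmvt(as.integer(ndraw), sigma = fit$s2 * solve(fit$xtx), df = 1,
                  delta = as.numeric(fit$beta_hat), type = "shifted")
  }, seed = if (is.null(seed)) 760519L else as.integer(seed) %% 2147483647L)
  inside <- vapply(systems, function(sys) {
    eta <- draws %*% t(sys$R_I)
    rowSums(eta > matrix(sys$r_I, nrow(eta), ncol(eta), byrow = TRUE)) ==
      nrow(sys$R_I)
  }, logical(nrow(draws)))
  for (i in seq_len(length(systems) - 1L)) for (j in (i + 1L):length(systems)) {
    if (any(inside[, i] & inside[, j]))
      stop("order hypotheses '", systems[[i]]$source, "' and '",
           systems[[j]]$source, "' overlap; the complement construction ",
           "requires disjoint order hypotheses — reformulate them",
           call. = FALSE)
  }
  invisible(TRUE)
}

run_confirmatory <- function(fit, hyp, priorprob, mcrep, seed) {
  systems <- parse_hypotheses(hyp, fit$coef_names)
  seeds <- derive_seeds(seed, length(systems))
  terms <- Map(function(sys, s) dispatch_bf(fit, sys, mcrep, s),
               systems, as.list(seeds))
  eq_free <- vapply(systems, function(s) nrow(s$R_E) == 0L, logical(1))
  check_disjoint(fit, systems[eq_free], seed)
  comp <- bf_complement(terms[eq_free],
                        source = if (length(systems) == 1L) "Not H1"
                                 else paste0("Not H1-H", length(systems)))
  complement_added <- !is.null(comp)
  if (complement_added) terms <- c(terms, list(comp))
  labels <- vapply(terms, `[[`, character(1), "label")
  B <- setNames(vapply(terms, `[[`, numeric(1), "B"), labels)
  prior <- if (identical(priorprob, "equal")) rep(1 / length(B), length(B))
           else {
             p <- as.numeric(priorprob)
             if (length(p) != length(B))
               stop("priorprob must be 'equal' or have length ", length(B),
                    " (", length(systems), " hypotheses",
                    if (complement_added) " plus the complement", ")")
             p / sum(p)
           }
  post <- posterior_probabilities(B, prior)
  structure(list(type = "confirmatory",
                 hypotheses = data.frame(
                   label = labels,
                   text = vapply(terms, `[[`, character(1), "source"),
                   stringsAsFactors = FALSE),
                 b_u = B,
                 prior_prob = setNames(prior, labels),
                 post_prob = post,
                 BF_matrix = bf_pairwise_matrix(B),
                 BF_computation = computation_table(terms, post),
                 BFu_CI = interval_table(terms),
                 complement_added = complement_added,
                 mcrep = mcrep, seed = seed, fit = fit, terms = terms),
            class = "bf_test")
}

run_exploratory <- function(fit, mcrep, seed) {
  cn <- fit$coef_names
  post <- matrix(NA_real_, length(cn), 3L,
                 dimnames = list(cn, c("X < 0", "X = 0", "X > 0")))
  mats <- setNames(vector("list", length(cn)), cn)
  for (j in seq_along(cn)) {
    triple <- exploratory_hypotheses(cn[j], cn)
    terms <- lapply(triple, function(sys) dispatch_bf(fit, sys, mcrep, NULL))
    B <- setNames(vapply(terms, `[[`, numeric(1), "B"), c("H1", "H2", "H3"))
    post[j, ] <- posterior_probabilities(B, "equal")
    mats[[j]] <- bf_pairwise_matrix(B)
  }
  structure(list(type = "exploratory",
                 hypotheses = data.frame(label = c("H1", "H2", "H3"),
                                         text = c("X < 0", "X = 0", "X > 0"),
                                         stringsAsFactors = FALSE),
                 post_prob = post,
                 prior_prob = setNames(rep(1 / 3, 3), c("H1", "H2", "H3")),
                 BF_matrix = mats,
                 BF_computation = NULL, BFu_CI = NULL,
                 complement_added = FALSE,
                 mcrep = mcrep, seed = seed, fit = fit),
            class = "bf_test")
}

prob_val <- function(p) if (is.null(p)) NA_real_ else p$value

computation_table <- function(terms, post) {
  rows <- lapply(seq_along(terms), function(i) {
    t <- terms[[i]]
    cE <- if (is.null(t$cE)) NA_real_ else t$cE
    fE <- if (is.null(t$fE)) NA_real_ else t$fE
    cI <- prob_val(t$cI); fI <- prob_val(t$fI)
    data.frame(`c(E)` = cE, `c(I|E)` = cI,
               c = if (is.na(cE)) NA_real_ else cE * ifelse(is.na(cI), 1, cI),
               `f(E)` = fE, `f(I|E)` = fI,
               f = if (is.na(fE)) NA_real_ else fE * ifelse(is.na(fI), 1, fI),
               `B(t,u)` = t$B, `PP(t)` = post[i],
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(terms, `[[`, character(1), "label")
  out
}

interval_table <- function(terms, level = 0.90) {
  if (!any(vapply(terms, uses_mc, logical(1)))) return(NULL)
  rows <- lapply(terms, function(t) {
    ci <- bf_interval(t, level)
    data.frame(`B(t,u)` = t$B,
               `lb (5%)` = if (is.null(ci)) NA_real_ else ci[["lower"]],
               `ub (95%)` = if (is.null(ci)) NA_real_ else ci[["upper"]],
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(terms, `[[`, character(1), "label")
  out
}
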