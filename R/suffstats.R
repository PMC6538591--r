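#' Sufficient statistics of a least-squares fit
#'
#' Fits the normal linear model `y = X beta + N(0, sigma^2 I)` by ordinary
#' least squares and returns the sufficient statistics that the default Bayes
#' factor consumes: the coefficient estimates `beta_hat`, the cross-product
#' matrix `X'X`, the residual sum of squares `s2`, the sample size `n`, the
#' number of design columns `k`, and the minimal fraction `b = (k+1)/n` used to
#' construct the implicit prior.
#'
#' Only the formula subset `response ~ x1 + x2 + ...` (optionally `- 1` to drop
#' the intercept) is supported: no interactions or in-formula transforms. Rows
#' with missing values in the used columns are dropped with a warning. With
#' `standardize = TRUE` every used column (response and predictors, never the
#' intercept) is centred and scaled to unit standard deviation before fitting,
#' which puts all coefficients on a common scale when they are compared against
#' each other.
#'
#' @param formula model formula naming the response and predictor columns.
#' @param data a data frame (or coercible) containing the named columns.
#' @param standardize logical; standardize response and predictors first.
#' @return An object of class `"linreg_stats"`: a list with elements
#'   `coef_names`, `beta_hat`, `xtx`, `s2`, `n`, `k` and `fraction_b`.
#' @examples
#' d <- sim_regression(40, beta = c(0.5, 0.2), seed = 1)
#' fit <- linreg_stats(y ~ x1 + x2, d)
#' fit$beta_hat
#' @seealso [linreg_stats_from_summary()], [bf_test()]
#' @export
linreg_stats <- function(formula, data, standardize = FALSE) {
  formula <- as.formula(formula)
  data <- as.data.frame(data)
  mf <- model.frame(formula, data, na.action = NULL)
  keep <- complete.cases(mf)
  if (!all(keep)) {
    warning(sprintf("dropped %d row(s) with missing values", sum(!keep)))
    mf <- mf[keep, , drop = FALSE]
  }
  if (standardize) {
    for (j in seq_along(mf)) {
      v <- mf[[j]]
      if (!is.numeric(v))
        stop("standardize requires numeric columns; '", names(mf)[j], "' is not numeric")
      s <- sd(v)
      if (!is.finite(s) || s == 0)
        stop("cannot standardize zero-variance column '", names(mf)[j], "'")
      mf[[j]] <- (v - mean(v)) / s
    }
  }
  y <- model.response(mf)
  if (!is.numeric(y)) stop("response must be numeric")
  X <- model.matrix(attr(mf, "terms"), mf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta_hat <- drop(qr.coef(qx, y))
  res <- y - drop(X %*% beta_hat)
  new_linreg_stats(beta_hat = beta_hat, xtx = crossprod(X),
                   s2 = sum(res^2), n = nrow(X), names = colnames(X))
}

#' Build sufficient statistics from precomputed summaries
#'
#' Constructs the same object as [linreg_stats()] from externally supplied
#' summaries, so the test can be run without access to the raw data. Two
#' datasets with identical `(beta_hat, s2, X'X, n)` yield identical Bayes
#' factors.
#'
#' @param beta_hat numeric vector of least-squares estimates (length `k`).
#' @param xtx `k x k` symmetric positive-definite cross-product matrix `X'X`.
#' @param s2 residual *sum of squares* (not a variance estimate).
#' @param n sample size; must exceed `k`.
#' @param names optional coefficient names; defaults to names of `beta_hat`
#'   or `b1, b2, ...`.
#' @return An object of class `"linreg_stats"`.
#' @export
linreg_stats_from_summary <- function(beta_hat, xtx, s2, n, names = NULL) {
  beta_hat <- drop(as.numeric(beta_hat))
  xtx <- as.matrix(xtx)
  if (is.null(names)) {
    names <- if (!is.null(colnames(xtx))) colnames(xtx)
             else paste0("b", seq_along(beta_hat))
  }
  new_linreg_stats(beta_hat, xtx, s2, n, names)
}

new_linreg_stats <- function(beta_hat, xtx, s2, n, names) {
  k <- length(beta_hat)
  if (!is.matrix(xtx) || any(dim(xtx) != k))
    stop("xtx must be a ", k, " x ", k, " matrix")
  if (length(names) != k) stop("names must have length ", k)
  if (!is_spd(xtx))
    stop("xtx must be symmetric positive definite (full column rank design)")
  if (!is.numeric(s2) || length(s2) != 1L || s2 <= 0)
    stop("s2 must be a positive residual sum of squares (perfect fits are rejected)")
  n <- as.integer(n)
  if (n <= k)
    stop("need n > k; got n = ", n, ", k = ", k)
  dimnames(xtx) <- list(names, names)
  structure(list(coef_names = names,
                 beta_hat = setNames(as.numeric(beta_hat), names),
                 xtx = xtx, s2 = as.numeric(s2), n = n, k = k,
                 fraction_b = (k + 1) / n),
            class = "linreg_stats")
}

# Extract sufficient statistics from a fitted stats::lm object.
as_linreg_stats <- function(object) {
  if (inherits(object, "linreg_stats")) return(object)
  if (!inherits(object, "lm")) stop("cannot extract regression statistics from class ",
                                    paste(class(object), collapse = "/"))
  cf <- coef(object)
  if (anyNA(cf)) stop("fitted model is rank deficient (NA coefficients): ",
                      paste(names(cf)[is.na(cf)], collapse = ", "))
  X <- model.matrix(object)
  new_linreg_stats(cf, crossprod(X), sum(stats::residuals(object)^2),
                   nrow(X), names(cf))
}

#' @export
print.linreg_stats <- function(x, ...) {
  cat("Linear model sufficient statistics (n = ", x$n, ", k = ", x$k,
      ", b = (k+1)/n = ", format(x$fraction_b, digits = 4), ")\n", sep = "")
  print(round(x$beta_hat, 4))
  cat("residual sum of squares:", format(x$s2, digits = 6), "\n")
  invisible(x)
}
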