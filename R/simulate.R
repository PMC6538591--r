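# Deterministic synthetic regression data for tests and examples.

#' Simulate a regression dataset
#'
#' Draws predictors from a zero-mean multivariate normal distribution with
#' the requested correlation structure and generates
#' `y = intercept + X beta + sigma * noise`. Fully reproducible from `seed`.
#'
#' @param n number of rows; must exceed `length(beta) + 1`.
#' @param beta true predictor coefficients (length `p`); the columns are named
#'   `x1, ..., xp` (or `names(beta)` when set).
#' @param sigma error standard deviation. `sigma = 0` is permitted here but
#'   produces a perfect fit that the model-fitting step rejects; a warning is
#'   issued.
#' @param intercept true intercept (default 0).
#' @param corr `p x p` predictor correlation matrix (positive definite, unit
#'   diagonal); identity when `NULL`.
#' @param seed optional integer seed.
#' @return A data frame with columns `y, x1, ..., xp`.
#' @examples
#' d <- sim_regression(100, beta = c(1, 0.5, 0.2), seed = 42)
#' coef(lm(y ~ x1 + x2 + x3, d))
#' @export
sim_regression <- function(n, beta, sigma = 1, intercept = 0, corr = NULL,
                           seed = NULL) {
  p <- length(beta)
  if (n <= p + 1L) stop("need n > length(beta) + 1")
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0)
    warning("sigma = 0 gives a perfect fit; downstream fitting rejects s2 = 0")
  if (is.null(corr)) corr <- diag(p)
  corr <- as.matrix(corr)
  if (any(dim(corr) != p) || max(abs(diag(corr) - 1)) > 1e-12 || !is_spd(corr))
    stop("corr must be a positive-definite correlation matrix with unit diagonal")
  if (!is.null(seed)) set.seed(as.integer(seed))
  Z <- matrix(rnorm(n * p), n, p)
  X <- Z %*% chol(corr)
  y <- intercept + drop(X %*% beta) + sigma * rnorm(n)
  nms <- if (!is.null(names(beta))) names(beta) else paste0("x", seq_len(p))
  out <- data.frame(y = y, X)
  names(out) <- c("y", nms)
  out
}

#' Construct a dataset with exactly prescribed least-squares statistics
#'
#' Builds `X` with `X'X` equal to `xtx` (via a Cholesky factor padded with
#' zero rows, rotated so that the first column is exactly a column of ones
#' when `intercept = TRUE`) and `y = X beta_hat + e` with the residual `e`
#' orthogonal to all columns of `X` and `||e||^2 = s2`. Fitting the returned
#' data therefore reproduces `(beta_hat, s2, X'X, n)` to machine precision,
#' for any seed: the seed only changes which orthogonal residual direction is
#' used, so all downstream Bayes factors are seed-independent.
#'
#' @param beta_hat target coefficient estimates (length `k`; the first entry
#'   is the intercept when `intercept = TRUE`).
#' @param s2 target residual sum of squares (positive).
#' @param xtx target `k x k` cross-product matrix (positive definite). With
#'   `intercept = TRUE` its first row/column corresponds to the column of ones,
#'   so `xtx[1, 1]` must equal `n`.
#' @param n number of rows; must be at least `k + 1` so a residual direction
#'   exists.
#' @param intercept whether the first design column is an intercept of ones
#'   (the returned data frame then omits it; the model formula adds it back).
#' @param seed optional integer seed.
#' @return A data frame with columns `y, x1, ...` ready for
#'   [linreg_stats()] with formula `y ~ x1 + ...` (append `- 1` when
#'   `intercept = FALSE`).
#' @examples
#' d <- sim_exact_mle(c(0.7, 0.03), s2 = 3, xtx = diag(2) * 5, n = 10,
#'                    intercept = FALSE, seed = 1)
#' linreg_stats(y ~ x1 + x2 - 1, d)$beta_hat
#' @export
sim_exact_mle <- function(beta_hat, s2, xtx, n, intercept = TRUE,
                          seed = NULL) {
  k <- length(beta_hat)
  xtx <- as.matrix(xtx)
  if (any(dim(xtx) != k)) stop("xtx must be ", k, " x ", k)
  if (!is_spd(xtx)) stop("xtx must be symmetric positive definite")
  if (s2 <= 0) stop("s2 must be positive")
  if (n < k + 1L)
    stop("need n >= k + 1 so that an orthogonal residual direction exists")
  if (intercept && abs(xtx[1, 1] - n) > 1e-8)
    stop("with an intercept, xtx[1, 1] must equal n (it is the squared norm ",
         "of the column of ones)")
  X <- rbind(chol(xtx), matrix(0, n - k, k))
  if (intercept) {
    # Householder rotation sending the first column to the ones vector;
    # orthogonal, so X'X is preserved exactly.
    u <- X[, 1] / sqrt(sum(X[, 1]^2))
    w <- rep(1 / sqrt(n), n)
    h <- u - w
    if (sqrt(sum(h^2)) > 1e-14) {
      X <- X - 2 * h %*% (crossprod(h, X)) / sum(h^2)
    }
    X[, 1] <- 1  # remove rounding residue; exact by construction
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  A <- crossprod(X)
  repeat {
    e <- rnorm(n)
    for (i in 1:2) e <- e - X %*% solve(A, crossprod(X, e))  # twice for accuracy
    nrm <- sqrt(sum(e^2))
    if (nrm > 1e-8) break
  }
  e <- drop(e) * sqrt(s2) / nrm
  y <- drop(X %*% beta_hat) + e
  nms <- if (!is.null(names(beta_hat))) names(beta_hat) else
    c(if (intercept) "(Intercept)" else NULL,
      paste0("x", seq_len(k - intercept)))
  keep <- if (intercept) seq_len(k)[-1L] else seq_len(k)
  out <- data.frame(y = y)
  if (length(keep)) {
    out <- cbind(out, as.data.frame(X[, keep, drop = FALSE]))
    names(out) <- c("y", nms[keep])
  }
  out
}
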