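# Reparameterization xi = T beta separating equality-constrained directions
# (xi_E = R_E beta) from the remaining free directions (xi_I = D beta).

#' Complement basis for the equality constraints
#'
#' Selects `k - q_E` linearly independent rows of the projector
#' `P = I_k - R_E'(R_E R_E')^{-1} R_E` so that stacking `R_E` over the
#' selection gives an invertible transformation `T`. Rows are chosen by a
#' deterministic greedy sweep in row order, which makes the construction
#' reproducible; the resulting Bayes factors are invariant to which full-rank
#' selection is made.
#'
#' @param R_E equality coefficient matrix with full row rank `q_E < k`
#'   (`q_E = 0` returns the identity).
#' @return A `(k - q_E) x k` matrix `D`.
#' @export
build_complement_basis <- function(R_E) {
  R_E <- as.matrix(R_E)
  k <- ncol(R_E); qE <- nrow(R_E)
  if (qE == 0L) return(diag(k))
  if (mat_rank(R_E) < qE) stop("R_E must have full row rank")
  if (qE >= k)
    stop("equality constraints fully determine the coefficient vector; ",
         "no free directions remain")
  P <- diag(k) - t(R_E) %*% solve(R_E %*% t(R_E)) %*% R_E
  D <- NULL
  for (i in seq_len(k)) {
    cand <- rbind(D, P[i, ])
    if (mat_rank(cand) == nrow(cand)) D <- cand
    if (!is.null(D) && nrow(D) == k - qE) break
  }
  if (is.null(D) || nrow(D) != k - qE)
    stop("failed to extract a complement basis from the projector")
  unname(D)
}

#' Transform a constraint system to the xi parameterization
#'
#' Computes `T = rbind(R_E, D)`, the reduced inequality system
#' `Rtilde_I xi_I > rtilde_I` with `Rtilde_I = R_I D^-` and
#' `rtilde_I = r_I - R_I R_E^- r_E` (Moore-Penrose generalized inverses), the
#' rank of `Rtilde_I` (a deficient rank routes probability computation to
#' Monte Carlo), and the prior centre `mu0 = T R^- r` for the stacked system
#' `R = rbind(R_E, R_I)`, `r = c(r_E, r_I)` in minimum-norm form.
#'
#' @param sys a feasible `"constraint_system"` with `q_E < k`.
#' @param D optional replacement complement basis (any full-rank choice gives
#'   the same Bayes factors; used for invariance checks).
#' @return An object of class `"transformed_system"`.
#' @export
transform_system <- function(sys, D = NULL) {
  k <- ncol(sys$R_E)
  qE <- nrow(sys$R_E); qI <- nrow(sys$R_I)
  if (qE >= k && qI > 0L)
    stop("saturated equality system: transformation undefined (handled upstream)")
  if (qE == 0L) {
    if (is.null(D)) D <- diag(k)
    TT <- D
    Rt <- sys$R_I %*% pinv(D)
    rt <- sys$r_I
    R <- sys$R_I; r <- sys$r_I
  } else {
    if (is.null(D)) D <- build_complement_basis(sys$R_E)
    TT <- rbind(sys$R_E, D)
    if (abs(det(TT)) < 1e-12) stop("transformation T is singular")
    if (qI > 0L) {
      Rt <- sys$R_I %*% pinv(D)
      rt <- drop(sys$r_I - sys$R_I %*% pinv(sys$R_E) %*% sys$r_E)
    } else {
      Rt <- empty_rows(k - qE); rt <- numeric()
    }
    R <- rbind(sys$R_E, sys$R_I); r <- c(sys$r_E, sys$r_I)
  }
  mu0 <- drop(TT %*% pinv(R) %*% r)
  if (qE > 0L && max(abs(mu0[seq_len(qE)] - sys$r_E)) > 1e-10 * max(1, max(abs(sys$r_E))))
    warning("prior centre does not reproduce r_E in its equality block")
  structure(list(T = TT, D = D,
                 Rtilde_I = as.matrix(Rt), rtilde_I = rt,
                 mu0 = mu0, rank_RtildeI = mat_rank(Rt),
                 q_E = qE, q_I = qI, k = k),
            class = "transformed_system")
}
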