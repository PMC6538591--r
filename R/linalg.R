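# Small linear-algebra helpers shared across modules.

# Moore-Penrose pseudo-inverse via SVD; cutoff max(dim) * eps * sigma_max.
pinv <- function(A, tol = NULL) {
  A <- as.matrix(A)
  if (length(A) == 0L) return(t(A))
  sv <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, pos, drop = FALSE] %*% ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
}

mat_rank <- function(A, tol = NULL) {
  A <- as.matrix(A)
  if (length(A) == 0L || nrow(A) == 0L) return(0L)
  d <- svd(A, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(d, 0)
  sum(d > tol)
}

# Orthonormal basis (columns) of the null space of A; identity-like basis if A
# has no rows.
null_basis <- function(A, k = ncol(A)) {
  if (is.null(A) || nrow(A) == 0L) return(diag(k))
  sv <- svd(A, nv = k)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r >= k) return(matrix(0, k, 0))
  sv$v[, (r + 1L):k, drop = FALSE]
}

is_spd <- function(A, tol = 1e-10) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) return(FALSE)
  if (max(abs(A - t(A))) > tol * max(1, max(abs(A)))) return(FALSE)
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(abs(ev), 1e-300)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# Used so quasi-Monte-Carlo rectangle probabilities are reproducible without
# consuming the user-visible random stream.
with_preserved_rng <- function(code, seed = 632051L) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
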