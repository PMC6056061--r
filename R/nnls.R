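# Non-negative least squares for multiple right-hand sides via block
# principal pivoting (Kim & Park style). This is the inner solver of the
# alternating factorization and is exercised against a multiplicative-update
# oracle in the test suite.

#' Non-negative least squares, multiple right-hand sides
#'
#' Solves `min_X || C X - B ||_F^2 subject to X >= 0` column-wise through the
#' normal equations `(C'C) X = C'B` using block principal pivoting. Columns
#' sharing a passive-set pattern are solved together, so the per-iteration
#' cost is a handful of small Cholesky solves regardless of the number of
#' right-hand sides.
#'
#' @param CtC q x q cross-product matrix `t(C) %*% C` (must be positive
#'   definite; add a ridge upstream if needed).
#' @param CtB q x r matrix `t(C) %*% B`.
#' @param max_outer Safety cap on pivoting rounds.
#' @param tol Dual/primal feasibility tolerance.
#' @return q x r non-negative solution matrix.
#' @export
nnls_bpp <- function(CtC, CtB, max_outer = 100L, tol = 1e-10) {
  q <- nrow(CtC)
  if (is.vector(CtB)) CtB <- matrix(CtB, nrow = q)
  r <- ncol(CtB)
  X <- matrix(0, q, r)
  Y <- -CtB                       # dual: CtC X - CtB at X = 0
  P <- matrix(FALSE, q, r)        # passive (free) set
  n_backup <- rep(3L, r)          # remaining full exchanges before fallback
  n_inf_prev <- rep(q + 1L, r)

  solve_groups <- function(P, X, cols) {
    # group columns by identical passive-set pattern
    keys <- apply(P[, cols, drop = FALSE], 2, function(z) paste(which(z), collapse = ","))
    for (k in unique(keys)) {
      grp <- cols[keys == k]
      F <- P[, grp[1]]
      if (!any(F)) { X[, grp] <- 0; next }
      sol <- tryCatch(
        solve(CtC[F, F, drop = FALSE], CtB[F, grp, drop = FALSE]),
        error = function(e)
          solve(CtC[F, F, drop = FALSE] + diag(1e-10, sum(F)),
                CtB[F, grp, drop = FALSE]))
      Xg <- matrix(0, q, length(grp))
      Xg[F, ] <- sol
      X[, grp] <- Xg
    }
    X
  }

  active_cols <- seq_len(r)
  for (outer in seq_len(max_outer)) {
    V <- (P & X < -tol) | (!P & Y < -tol)
    n_inf <- colSums(V)
    active_cols <- which(n_inf > 0)
    if (length(active_cols) == 0) break
    for (j in active_cols) {
      if (n_inf[j] < n_inf_prev[j]) {
        n_inf_prev[j] <- n_inf[j]
        n_backup[j] <- 3L
        P[V[, j], j] <- !P[V[, j], j]
      } else if (n_backup[j] > 0L) {
        n_backup[j] <- n_backup[j] - 1L
        P[V[, j], j] <- !P[V[, j], j]
      } else {
        # single exchange of the largest-index infeasible variable
        i <- max(which(V[, j]))
        P[i, j] <- !P[i, j]
      }
    }
    X[, active_cols] <- 0
    X <- solve_groups(P, X, active_cols)
    G <- CtC %*% X[, active_cols, drop = FALSE] - CtB[, active_cols, drop = FALSE]
    Ya <- G
    Ya[P[, active_cols, drop = FALSE]] <- 0
    Y[, active_cols] <- Ya
    Xa <- X[, active_cols, drop = FALSE]
    Xa[!P[, active_cols, drop = FALSE]] <- 0
    X[, active_cols] <- Xa
  }
  X[X < 0 & X > -tol] <- 0
  pmax(X, 0)
}
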