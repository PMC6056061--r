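# Independent oracles used across the suite. These deliberately do not share
# code with the package implementation.

# Lee-Seung multiplicative updates for min ||A - WH||_F^2 (alpha = beta = 0),
# from a given initialization. Serves as the independent solver oracle.
mu_nmf <- function(A, W, H, n_iter = 2000, eps = 1e-12) {
  for (i in seq_len(n_iter)) {
    H <- H * crossprod(W, A) / (crossprod(W) %*% H + eps)
    W <- W * tcrossprod(A, H) / (W %*% tcrossprod(H) + eps)
  }
  list(W = W, H = H, objective = 0.5 * sum((A - W %*% H)^2))
}

# Exhaustive minimum-cost assignment for small n.
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- all_permutations(n)
  costs <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(assignment = perms[which.min(costs), ], cost = min(costs))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# Tiny deterministic cohort reused across tests (memoised per session).
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(n_subjects = 3, n_regions = 20,
                                n_subgraphs = 2, seed = 42)
    cache
  }
})

# A small random non-negative configuration-like matrix.
rand_nonneg <- function(nr, nc, seed = 1) {
  set.seed(seed)
  matrix(runif(nr * nc), nr, nc)
}

expect_monotone_trace <- function(trace, rel_tol = 1e-8) {
  if (length(trace) > 1) {
    rel_inc <- diff(trace) / pmax(abs(trace[-length(trace)]), .Machine$double.eps)
    testthat::expect_lte(max(rel_inc), rel_tol)
  } else {
    testthat::succeed()
  }
}
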