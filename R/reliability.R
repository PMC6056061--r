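# Split-half test-retest of subgraphs: independent decompositions of the two
# halves, optimal one-to-one matching by the Hungarian algorithm on Euclidean
# distances between subgraph edge vectors, and a similarity null built from
# all non-assigned pairs.

#' Minimum-cost linear assignment (Hungarian algorithm)
#'
#' Solves the square assignment problem in O(n^3) by shortest augmenting
#' paths with dual potentials. Verified against exhaustive enumeration in the
#' test suite.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  n <- nrow(cost)
  # column n+1 is the virtual "unassigned" column holding the row being placed
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1)      # column potentials (n+1 = virtual)
  p <- integer(n + 1)      # p[j] = row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == n + 1L) i else p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0) assignment[p[j]] <- j
  assignment
}

#' Split a configuration matrix into two block-halves
#'
#' Partitions observation columns by block index: blocks `1..at` versus
#' `(at+1)..max`. Both halves are re-normalized independently when
#' `normalize = TRUE` (the input should then be un-normalized).
#'
#' @param config A `config_matrix`.
#' @param at Last block index of the first half (default: half the blocks).
#' @param normalize Re-apply [normalize_configuration()] to each half.
#' @return List with `first` and `second` `config_matrix` halves.
#' @export
split_half <- function(config, at = NULL, normalize = TRUE) {
  stopifnot(inherits(config, "config_matrix"))
  blocks <- sort(unique(config$obs_meta$block))
  if (length(blocks) < 2) stop("need at least 2 blocks per condition to split")
  if (is.null(at)) {
    if (length(blocks) %% 2 == 1)
      stop("odd number of blocks; supply a split point `at`")
    at <- blocks[length(blocks) / 2]
  }
  take <- function(keep) {
    half <- config
    half$mat <- config$mat[, keep, drop = FALSE]
    half$obs_meta <- config$obs_meta[keep, ]
    rownames(half$obs_meta) <- NULL
    half$normalized <- FALSE
    if (normalize) half <- normalize_configuration(half)
    half
  }
  first <- config$obs_meta$block <= at
  list(first = take(first), second = take(!first))
}

#' Match two subgraph sets by minimum Euclidean assignment
#'
#' Cost `C[i, j]` is the Euclidean distance between subgraph edge vectors
#' `W1[, i]` and `W2[, j]`; the Hungarian algorithm finds the one-to-one
#' assignment of minimum total cost. Matched-pair Pearson correlations are
#' computed on the edge vectors.
#'
#' @param W1,W2 E x m subgraph matrices (equal m required).
#' @return A `subgraph_match`: list with `assignment` (column of W2 matched
#'   to each column of W1), `cost` (matrix), `total_cost`, `pairs`
#'   (data.frame i, j, distance, correlation).
#' @export
match_subgraphs <- function(W1, W2) {
  W1 <- as_W_matrix(W1); W2 <- as_W_matrix(W2)
  if (ncol(W1) != ncol(W2)) stop("subgraph counts differ")
  if (nrow(W1) != nrow(W2)) stop("edge counts differ")
  m <- ncol(W1)
  cost <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    cost[i, j] <- sqrt(sum((W1[, i] - W2[, j])^2))
  assignment <- solve_assignment(cost)
  safe_cor <- function(x, y) {
    # a dead (constant) subgraph column shares no pattern with anything
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }
  pairs <- data.frame(
    i = seq_len(m), j = assignment,
    distance = cost[cbind(seq_len(m), assignment)],
    correlation = vapply(seq_len(m), function(i)
      safe_cor(W1[, i], W2[, assignment[i]]), numeric(1)))
  structure(list(assignment = assignment, cost = cost,
                 total_cost = sum(pairs$distance), pairs = pairs,
                 W1 = W1, W2 = W2),
            class = "subgraph_match")
}

#' @export
print.subgraph_match <- function(x, ...) {
  cat(sprintf("subgraph_match: %d pairs, total cost %.4g, correlations [%.3f, %.3f]\n",
              nrow(x$pairs), x$total_cost,
              min(x$pairs$correlation), max(x$pairs$correlation)))
  invisible(x)
}

#' Similarity significance against non-assigned pairs
#'
#' The null distribution is the set of Pearson correlations of all
#' `m * (m - 1)` non-assigned (ordered) subgraph pairs; a matched pair is
#' flagged reliable when its correlation exceeds the null's upper bound at
#' level `alpha`, Bonferroni corrected over the `m` matched pairs.
#'
#' @param match A [match_subgraphs()] result.
#' @param alpha Family-wise level (default 0.05).
#' @return Data.frame pair (i), matched_j, correlation, null_bound, reliable;
#'   the null correlations are attached as attribute `"null"`.
#' @export
similarity_null_test <- function(match, alpha = 0.05) {
  stopifnot(inherits(match, "subgraph_match"))
  m <- nrow(match$pairs)
  if (m < 2) stop("need m >= 2 for a non-assigned null")
  cors <- stats::cor(match$W1, match$W2)      # m x m Pearson
  assigned <- cbind(seq_len(m), match$assignment)
  null_mask <- matrix(TRUE, m, m)
  null_mask[assigned] <- FALSE
  null <- cors[null_mask]
  bound <- stats::quantile(null, 1 - alpha / m, names = FALSE)
  out <- data.frame(pair = seq_len(m), matched_j = match$assignment,
                    correlation = match$pairs$correlation,
                    null_bound = bound,
                    reliable = match$pairs$correlation > bound)
  attr(out, "null") <- null
  out
}

#' Split-half reliability pipeline
#'
#' Splits the (raw) configuration matrix by block halves, decomposes each
#' half with the same parameters (different derived seeds, recorded), matches
#' the two subgraph sets, and runs the non-assigned-pair null test.
#'
#' @param config An un-normalized `config_matrix`.
#' @param params An [nmf_params()] object (the full-run optimum).
#' @param at Split point passed to [split_half()].
#' @param alpha Level for [similarity_null_test()].
#' @return List with `match`, `reliability` (the null-test table), `seeds`.
#' @export
reliability_pipeline <- function(config, params, at = NULL, alpha = 0.05) {
  halves <- split_half(config, at = at, normalize = TRUE)
  seeds <- derive_seeds(params$seed, 2L, salt = 67L)
  p1 <- params; p1$seed <- seeds[1]
  p2 <- params; p2$seed <- seeds[2]
  fit1 <- fit_nmf(halves$first, p1)
  fit2 <- fit_nmf(halves$second, p2)
  match <- match_subgraphs(fit1$W, fit2$W)
  rel <- similarity_null_test(match, alpha = alpha)
  list(match = match, reliability = rel, seeds = seeds,
       fit_first = fit1, fit_second = fit2)
}
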