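#' @keywords internal
"_PACKAGE"

# Upper-triangle edge ordering used everywhere: pairs (i, j) with i < j,
# row-major (i ascending, then j). Region ids are 1-based.

#' Edge index for an undirected graph on `n` nodes
#'
#' Enumerates the \eqn{n(n-1)/2} unordered node pairs in the canonical order
#' used by the configuration matrix: upper triangle, \eqn{i < j}, row-major.
#'
#' @param n Number of nodes (regions).
#' @return A data.frame with integer columns `i` and `j` (1-based region ids).
#' @export
#' @examples
#' edge_index(4)
edge_index <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 2)
  n <- as.integer(n)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  data.frame(i = i, j = as.integer(j))
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' @param M Symmetric numeric matrix (diagonal ignored).
#' @return Numeric vector of length `nrow(M) * (nrow(M) - 1) / 2` in
#'   canonical edge order (see [edge_index()]).
#' @export
vectorize_edges <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  t(M)[lower.tri(M)]
}

#' Reconstitute a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_edges()]; the diagonal is set to zero.
#'
#' @param v Edge-weight vector in canonical order.
#' @param n Number of nodes; inferred from `length(v)` when missing.
#' @return An `n` x `n` symmetric matrix with zero diagonal.
#' @export
edges_to_matrix <- function(v, n = NULL) {
  if (is.null(n)) {
    n <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (abs(n - round(n)) > 1e-8)
      stop("length(v) is not a triangular number; supply n explicitly")
    n <- as.integer(round(n))
  }
  stopifnot(length(v) == n * (n - 1) / 2)
  # column-major lower triangle of the transpose is the row-major upper triangle
  Mt <- matrix(0, n, n)
  Mt[lower.tri(Mt)] <- v
  t(Mt) + Mt
}

# Derive a vector of child seeds from a master seed without disturbing the
# caller's RNG state. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seeds <- function(seed, n, salt = 0L) {
  stopifnot(n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.numeric(seed) + 97003 * as.numeric(salt)) %% 2147483647)
  sample.int(2147483646L, n)
}

# Evaluate expr under a local RNG seed, restoring caller state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Consistent lexicographic ordering of observation metadata.
order_observations <- function(meta) {
  order(meta$subject, meta$task, meta$condition, meta$block, meta$sign_channel)
}

# Two-sided paired t that degrades gracefully when all differences are equal
# (sd of differences 0): statistic 0 and p 1 for a zero mean difference,
# +/-Inf statistic and p ~ 0 otherwise.
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  stopifnot(n >= 2)
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) return(list(statistic = 0, df = n - 1, p.value = 1))
    return(list(statistic = sign(m) * Inf, df = n - 1, p.value = 0))
  }
  stat <- m / (s / sqrt(n))
  list(statistic = stat, df = n - 1,
       p.value = 2 * stats::pt(-abs(stat), df = n - 1))
}
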