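# Linking subgraph expression to behavioral performance: reaction-time cost,
# expression-performance correlations, and performance participation scores
# with permutation nulls.

#' Per-subject reaction-time cost
#'
#' Mean reaction time over correct trials per block; cost is the mean over
#' high-demand blocks minus the mean over low-demand blocks (lower is better
#' performance). Subjects with zero correct trials in either condition are
#' excluded with a message. With `per_pair = TRUE` the cost is instead the
#' mean over block-index-matched (high_i - low_i) differences.
#'
#' @param behavior A behavior table (subject, task, condition, block, trial,
#'   rt_ms, correct).
#' @param task Task label to restrict to.
#' @param per_pair Pair blocks by index instead of differencing condition
#'   means (equivalent when block counts match and all blocks are present).
#' @return Data.frame subject, cost_ms.
#' @export
reaction_time_cost <- function(behavior, task, per_pair = FALSE) {
  b <- behavior[behavior$task == task & behavior$correct == 1 &
                  behavior$condition %in% c("low", "high"), ]
  subjects <- sort(unique(behavior$subject[behavior$task == task]))
  rows <- lapply(subjects, function(s) {
    bs <- b[b$subject == s, ]
    block_means <- tapply(bs$rt_ms, list(bs$condition, bs$block), mean)
    if (!all(c("low", "high") %in% rownames(block_means)) ||
        all(is.na(block_means["low", ])) || all(is.na(block_means["high", ]))) {
      message(sprintf("subject %s excluded: no correct trials in a condition", s))
      return(NULL)
    }
    if (per_pair) {
      d <- block_means["high", ] - block_means["low", ]
      cost <- mean(d, na.rm = TRUE)
    } else {
      cost <- mean(block_means["high", ], na.rm = TRUE) -
        mean(block_means["low", ], na.rm = TRUE)
    }
    data.frame(subject = s, cost_ms = cost)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation of subgraph expression with reaction-time cost
#'
#' For each subgraph: Spearman's rho between per-subject relative expression
#' (averaged over blocks of one demand condition of one task) and the
#' per-subject reaction-time cost. Positive rho means greater negative
#' expression associates with lower cost. Raw p-values are reported
#' (uncorrected); a Benjamini-Hochberg column is included for convenience.
#'
#' @param summary An [relative_expression()] result (or a data.frame with
#'   columns subject, task, condition, block, subgraph, relative).
#' @param costs A [reaction_time_cost()] result.
#' @param task Task label.
#' @param condition `"low"` or `"high"`.
#' @return Data.frame subgraph, rho, p, p_adj.
#' @export
expression_performance_correlation <- function(summary, costs, task,
                                               condition = c("low", "high")) {
  condition <- match.arg(condition)
  tab <- if (inherits(summary, "expression_summary")) summary$table else summary
  tab <- tab[tab$task == task & tab$condition == condition, ]
  if (length(unique(costs$subject)) < 5) stop("need at least 5 subjects")
  if (stats::sd(costs$cost_ms) == 0) stop("constant cost vector")
  ks <- sort(unique(tab$subgraph))
  rows <- lapply(ks, function(k) {
    tk <- tab[tab$subgraph == k, ]
    expr <- tapply(tk$relative, tk$subject, mean)
    common <- intersect(names(expr), as.character(costs$subject))
    x <- expr[common]
    y <- costs$cost_ms[match(common, as.character(costs$subject))]
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = length(x) < 10))
    data.frame(subgraph = k, rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

# Node strengths per subgraph from an E x m subgraph matrix: strength_k(i) =
# sum_j W_k[i, j]. Returns N x m.
node_strengths <- function(W, n_regions) {
  ei <- edge_index(n_regions)
  apply(W, 2, function(w) {
    s <- numeric(n_regions)
    agg_i <- tapply(w, ei$i, sum)
    agg_j <- tapply(w, ei$j, sum)
    s[as.integer(names(agg_i))] <- s[as.integer(names(agg_i))] + agg_i
    s[as.integer(names(agg_j))] <- s[as.integer(names(agg_j))] + agg_j
    s
  })
}

#' Performance participation scores
#'
#' Node strength of region `i` in subgraph `k` is the sum of that subgraph's
#' edge weights incident to `i`; the participation score is
#' `score(i) = sum_k rho_k * strength_k(i)`. Positive scores classify the
#' region as "disengaged" with better performance (anticorrelated dynamics),
#' negative as "engaged".
#'
#' @param W E x m non-negative subgraph matrix (columns = subgraphs), or a
#'   `subgraph_decomp` / `consensus_result`.
#' @param rho_vector One Spearman rho per subgraph.
#' @param n_regions Number of regions (needed when `W` is a plain matrix
#'   whose edge count does not determine N... it always does; optional).
#' @return A `participation_scores` data.frame: region, strengths (N x m
#'   matrix column), score, class.
#' @export
participation_score <- function(W, rho_vector, n_regions = NULL) {
  W <- as_W_matrix(W)
  if (ncol(W) != length(rho_vector)) stop("one rho per subgraph required")
  if (is.null(n_regions)) {
    n_regions <- (1 + sqrt(1 + 8 * nrow(W))) / 2
    n_regions <- as.integer(round(n_regions))
  }
  S <- node_strengths(W, n_regions)
  score <- as.numeric(S %*% rho_vector)
  out <- data.frame(region = seq_len(n_regions), score = score,
                    class = ifelse(score > 0, "disengaged",
                                   ifelse(score < 0, "engaged", "none")))
  attr(out, "strengths") <- S
  class(out) <- c("participation_scores", "data.frame")
  out
}

as_W_matrix <- function(W) {
  if (inherits(W, "subgraph_decomp")) return(W$W)
  if (inherits(W, "consensus_result")) return(W$W_consensus)
  if (is.numeric(W) && is.null(dim(W))) return(matrix(W, ncol = 1))
  stopifnot(is.matrix(W))
  W
}

#' Permutation null test of participation scores
#'
#' Each permutation independently shuffles every subgraph's edge weights over
#' node pairs and recomputes all regional participation scores. Regions whose
#' observed score falls outside the null's central 95% interval, Bonferroni
#' corrected over regions, are flagged significant.
#'
#' @param W E x m subgraph matrix (or decomposition object).
#' @param rho_vector One rho per subgraph.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param alpha Family-wise level (default 0.05).
#' @return Data.frame region, score, p (two-sided, plus-one), significant.
#' @export
participation_null_test <- function(W, rho_vector, n_perm = 10000L,
                                    seed = 1L, alpha = 0.05) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  W <- as_W_matrix(W)
  n_regions <- as.integer(round((1 + sqrt(1 + 8 * nrow(W))) / 2))
  obs <- participation_score(W, rho_vector, n_regions)$score
  ei <- edge_index(n_regions)
  # incidence: N x E, node i touches edge e
  inc <- matrix(0, n_regions, nrow(ei))
  inc[cbind(ei$i, seq_len(nrow(ei)))] <- 1
  inc[cbind(ei$j, seq_len(nrow(ei)))] <- 1
  null_scores <- with_seed(seed, {
    acc <- matrix(0, n_regions, n_perm)
    for (k in seq_len(ncol(W))) {
      P <- permute_edge_vectors(W[, k], n_perm)   # E x n_perm
      acc <- acc + rho_vector[k] * (inc %*% P)
    }
    acc
  })
  p <- vapply(seq_len(n_regions), function(i) {
    ge <- sum(null_scores[i, ] >= obs[i])
    le <- sum(null_scores[i, ] <= obs[i])
    min(1, 2 * (min(ge, le) + 1) / (n_perm + 1))
  }, numeric(1))
  data.frame(region = seq_len(n_regions), score = obs, p = p,
             significant = p < alpha / n_regions)
}
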