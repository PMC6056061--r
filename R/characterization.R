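# Subgraph expression dynamics (relative expression, hierarchy, contrasts)
# and topology (core-periphery structure, system interactions) with
# permutation significance.

#' Relative expression summary
#'
#' For every (subject, task, condition, block) cell, pairs a subgraph's
#' positive-channel and negative-channel expression coefficients and forms
#' the relative expression (positive minus negative). Subgraphs are ranked by
#' their cohort mean relative expression over task (non-fixation) blocks, in
#' decreasing order, and labelled `A`, `B`, ... accordingly.
#'
#' @param H m x T non-negative expression matrix.
#' @param obs_meta Observation metadata (one row per column of `H`, columns
#'   subject, task, condition, block, sign_channel).
#' @return An `expression_summary`: list with `table` (long data.frame with
#'   columns subject, task, condition, block, subgraph, positive, negative,
#'   relative) and `ranking` (data.frame subgraph, label, mean_relative,
#'   class = "positive"/"negative").
#' @export
relative_expression <- function(H, obs_meta) {
  stopifnot(ncol(H) == nrow(obs_meta))
  m <- nrow(H)
  pos_cols <- which(obs_meta$sign_channel == "pos")
  neg_cols <- which(obs_meta$sign_channel == "neg")
  keyv <- function(idx) paste(obs_meta$subject[idx], obs_meta$task[idx],
                              obs_meta$condition[idx], obs_meta$block[idx])
  kp <- keyv(pos_cols); kn <- keyv(neg_cols)
  match_np <- match(kp, kn)
  orphans <- c(kp[is.na(match_np)], setdiff(kn, kp))
  if (length(orphans) > 0)
    stop("missing sign-channel partner for cell(s): ",
         paste(utils::head(orphans, 3), collapse = "; "))
  neg_cols <- neg_cols[match_np]

  tab <- do.call(rbind, lapply(seq_len(m), function(k) {
    data.frame(subject = obs_meta$subject[pos_cols],
               task = obs_meta$task[pos_cols],
               condition = obs_meta$condition[pos_cols],
               block = obs_meta$block[pos_cols],
               subgraph = k,
               positive = H[k, pos_cols],
               negative = H[k, neg_cols])
  }))
  tab$relative <- tab$positive - tab$negative

  task_rows <- tab$condition != "fixation"
  mean_rel <- tapply(tab$relative[task_rows], tab$subgraph[task_rows], mean)
  ord <- order(mean_rel, decreasing = TRUE)
  ranking <- data.frame(
    subgraph = as.integer(names(mean_rel))[ord],
    label = LETTERS[seq_len(m)],
    mean_relative = as.numeric(mean_rel)[ord],
    class = ifelse(as.numeric(mean_rel)[ord] >= 0, "positive", "negative"))
  structure(list(table = tab, ranking = ranking),
            class = "expression_summary")
}

#' Core and periphery scores with the core-periphery index
#'
#' For a symmetric zero-diagonal subgraph matrix and a node-to-system
#' partition: for each system `s`, `core_s` is the sum of edge weights over
#' ordered within-system pairs divided by `|s|`, and `periphery_s` is the sum
#' over ordered pairs from `s` to the rest divided by `|s| * (N - |s|)`. The
#' index averages `(core_s - periphery_s) / (core_s + periphery_s)` over
#' systems (systems with `core_s + periphery_s = 0` contribute 0), and is
#' bounded in \[-1, +1\].
#'
#' @param W_k Symmetric non-negative matrix with zero diagonal (or an edge
#'   vector in canonical order).
#' @param partition A `system_partition`.
#' @return A list with `scores` (data.frame system, size, core, periphery)
#'   and `index`.
#' @export
core_periphery_index <- function(W_k, partition) {
  if (!is.matrix(W_k)) W_k <- edges_to_matrix(W_k)
  N <- nrow(W_k)
  stopifnot(length(partition$assignment) == N)
  if (any(diag(W_k) != 0)) stop("diagonal must be zero")
  sys <- partition$systems
  if (length(sys) < 2) stop("need at least 2 systems")
  sizes <- table(partition$assignment)
  if (any(sizes == 0)) stop("every system must be non-empty")
  if (any(sizes == N)) stop("a system covering all nodes has no periphery")

  scores <- do.call(rbind, lapply(sys, function(s) {
    in_s <- partition$assignment == s
    ns <- sum(in_s)
    core <- sum(W_k[in_s, in_s]) / ns
    periph <- sum(W_k[in_s, !in_s]) / (ns * (N - ns))
    data.frame(system = s, size = ns, core = core, periphery = periph)
  }))
  denom <- scores$core + scores$periphery
  term <- ifelse(denom == 0, 0, (scores$core - scores$periphery) / denom)
  list(scores = scores, index = mean(term))
}

# Permute a subgraph's edge weights uniformly over node pairs, preserving
# symmetry and the zero diagonal. Returns an edge-vector matrix E x n_perm.
permute_edge_vectors <- function(w_edges, n_perm) {
  E <- length(w_edges)
  vapply(seq_len(n_perm), function(i) w_edges[sample.int(E)],
         numeric(E))
}

#' Permutation test of per-system core and periphery scores
#'
#' Generates surrogate subgraphs by permuting edge weights uniformly over
#' node pairs and recomputing per-system core and periphery scores. One-sided
#' p-values use the plus-one estimator `(b + 1) / (n_perm + 1)` and are
#' Bonferroni-corrected (default factor: systems x 2 scores; scale up by the
#' number of subgraphs tested via `bonferroni_n`).
#'
#' @param W_k Symmetric subgraph matrix (or edge vector).
#' @param partition A `system_partition`.
#' @param n_perm Number of permutations (>= 100; reference uses 10000).
#' @param seed Integer seed.
#' @param bonferroni_n Correction factor (default `2 * n_systems`).
#' @return Data.frame per system: core, periphery, p_core, p_periphery,
#'   p_core_adj, p_periphery_adj.
#' @export
system_core_periphery_test <- function(W_k, partition, n_perm = 10000L,
                                       seed = 1L, bonferroni_n = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.matrix(W_k)) W_k <- edges_to_matrix(W_k)
  obs <- core_periphery_index(W_k, partition)$scores
  w <- vectorize_edges(W_k)
  N <- nrow(W_k)
  masks <- system_edge_masks(partition, N)
  if (is.null(bonferroni_n)) bonferroni_n <- 2L * nrow(obs)

  perm_scores <- with_seed(seed, {
    P <- permute_edge_vectors(w, n_perm)           # E x n_perm
    # within unordered edges count twice in the ordered core sum; each
    # between unordered edge appears once in the rectangular periphery sum
    core <- (masks$within %*% P) * (2 / masks$sizes)        # S x n_perm
    periph <- (masks$between %*% P) / (masks$sizes * (N - masks$sizes))
    list(core = core, periph = periph)
  })
  p_core <- vapply(seq_len(nrow(obs)), function(i)
    (sum(perm_scores$core[i, ] >= obs$core[i]) + 1) / (n_perm + 1), numeric(1))
  p_per <- vapply(seq_len(nrow(obs)), function(i)
    (sum(perm_scores$periph[i, ] >= obs$periphery[i]) + 1) / (n_perm + 1),
    numeric(1))
  data.frame(system = obs$system, size = obs$size,
             core = obs$core, periphery = obs$periphery,
             p_core = p_core, p_periphery = p_per,
             p_core_adj = pmin(1, p_core * bonferroni_n),
             p_periphery_adj = pmin(1, p_per * bonferroni_n))
}

# Per-system edge masks over the canonical edge vector: within[s, e] = 1 when
# edge e joins two nodes of system s; between[s, e] = 1 when exactly one
# endpoint is in s. An unordered within edge appears twice in the ordered
# core sum, hence the factor 2 applied by callers; same for between edges.
system_edge_masks <- function(partition, N) {
  ei <- edge_index(N)
  a <- partition$assignment
  sys <- partition$systems
  within <- t(vapply(sys, function(s)
    as.numeric(a[ei$i] == s & a[ei$j] == s), numeric(nrow(ei))))
  between <- t(vapply(sys, function(s)
    as.numeric(xor(a[ei$i] == s, a[ei$j] == s)), numeric(nrow(ei))))
  sizes <- as.numeric(table(a)[sys])
  list(within = within, between = between, sizes = sizes, edge_index = ei)
}

#' Permutation test of within- and between-system mean edge weights
#'
#' Like [system_core_periphery_test()] but the statistics are the mean
#' within-system edge weight and the mean between-system edge weight per
#' system (means over unordered pairs).
#'
#' @inheritParams system_core_periphery_test
#' @return Data.frame per system: within, between, p_within, p_between and
#'   Bonferroni-adjusted columns.
#' @export
system_interaction_test <- function(W_k, partition, n_perm = 10000L,
                                    seed = 1L, bonferroni_n = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.matrix(W_k)) W_k <- edges_to_matrix(W_k)
  N <- nrow(W_k)
  w <- vectorize_edges(W_k)
  masks <- system_edge_masks(partition, N)
  n_within <- rowSums(masks$within)
  n_between <- rowSums(masks$between)
  if (any(n_within == 0))
    stop("system with no within-system pairs (size 1)")
  obs_within <- as.numeric(masks$within %*% w) / n_within
  obs_between <- as.numeric(masks$between %*% w) / n_between
  if (is.null(bonferroni_n)) bonferroni_n <- 2L * length(obs_within)

  perms <- with_seed(seed, {
    P <- permute_edge_vectors(w, n_perm)
    list(within = (masks$within %*% P) / n_within,
         between = (masks$between %*% P) / n_between)
  })
  p_within <- vapply(seq_along(obs_within), function(i)
    (sum(perms$within[i, ] >= obs_within[i]) + 1) / (n_perm + 1), numeric(1))
  p_between <- vapply(seq_along(obs_between), function(i)
    (sum(perms$between[i, ] >= obs_between[i]) + 1) / (n_perm + 1), numeric(1))
  data.frame(system = partition$systems,
             within = obs_within, between = obs_between,
             p_within = p_within, p_between = p_between,
             p_within_adj = pmin(1, p_within * bonferroni_n),
             p_between_adj = pmin(1, p_between * bonferroni_n))
}

#' Spearman correlation of subgraph expression hierarchies
#'
#' Correlates the cohort-mean relative expression per subgraph between two
#' groupings of the summary table (e.g. the two tasks, or low vs high
#' demand). Ties use the average-rank convention; p-values use exact
#' enumeration below n = 10 and the t approximation otherwise.
#'
#' @param summary An [relative_expression()] result.
#' @param grouping_a,grouping_b Named filters, e.g. `list(task = "stroop")`
#'   or `list(condition = "low")`; fixation blocks are always excluded.
#' @return List with `rho`, `p.value`, and the two per-subgraph mean vectors.
#' @export
expression_hierarchy_correlation <- function(summary, grouping_a, grouping_b) {
  tab <- summary$table
  tab <- tab[tab$condition != "fixation", ]
  mean_by <- function(g) {
    keep <- rep(TRUE, nrow(tab))
    for (nm in names(g)) keep <- keep & tab[[nm]] == g[[nm]]
    as.numeric(tapply(tab$relative[keep], tab$subgraph[keep], mean))
  }
  a <- mean_by(grouping_a); b <- mean_by(grouping_b)
  if (length(a) < 3) stop("need at least 3 subgraphs")
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = length(a) < 10))
  list(rho = unname(ct$estimate), p.value = ct$p.value, mean_a = a, mean_b = b)
}

#' Per-subgraph paired contrasts of relative expression
#'
#' For every subgraph, a paired t-test across subjects compares per-subject
#' mean relative expression between two groups (e.g. the two tasks, or low vs
#' high demand within one task), with Benjamini-Hochberg FDR across
#' subgraphs.
#'
#' @param summary An [relative_expression()] result.
#' @param grouping_a,grouping_b Named filters as in
#'   [expression_hierarchy_correlation()].
#' @param fdr_q FDR level used for the `significant` flag (default 0.05).
#' @return A `contrast_result` data.frame: subgraph, statistic, df,
#'   mean_diff, p, p_adj, direction, significant.
#' @export
contrast_expression <- function(summary, grouping_a, grouping_b,
                                fdr_q = 0.05) {
  tab <- summary$table
  tab <- tab[tab$condition != "fixation", ]
  per_subject <- function(g, k) {
    keep <- tab$subgraph == k
    for (nm in names(g)) keep <- keep & tab[[nm]] == g[[nm]]
    tapply(tab$relative[keep], tab$subject[keep], mean)
  }
  ks <- sort(unique(tab$subgraph))
  rows <- lapply(ks, function(k) {
    a <- per_subject(grouping_a, k); b <- per_subject(grouping_b, k)
    stopifnot(identical(names(a), names(b)))
    if (length(a) < 2) stop("need at least 2 subjects")
    tt <- paired_t(a, b)
    data.frame(subgraph = k, statistic = tt$statistic, df = tt$df,
               mean_diff = mean(a - b), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$mean_diff >= 0, "a>b", "b>a")
  out$significant <- out$p_adj < fdr_q
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Edge-wise Fisher r-to-Z contrasts
#'
#' For each edge and sign channel, per-subject mean edge weights (magnitude
#' correlations) are Fisher r-to-Z transformed (`atanh`, clipped at
#' `1 - 1e-7` with a warning), compared between two column groups by paired
#' t-test across subjects, and FDR-corrected across edges per channel.
#'
#' @param config An *un-normalized* `config_matrix` (raw correlation
#'   magnitudes).
#' @param grouping_a,grouping_b Named filters over obs_meta columns, e.g.
#'   `list(task = "stroop")`.
#' @param fdr_q FDR level (default 0.05).
#' @return Data.frame per edge x channel: i, j, sign_channel, mean_dz,
#'   statistic, p, p_adj, significant.
#' @export
edge_contrast <- function(config, grouping_a, grouping_b, fdr_q = 0.05) {
  stopifnot(inherits(config, "config_matrix"))
  if (isTRUE(config$normalized))
    warning("edge_contrast expects raw (un-normalized) correlation magnitudes")
  meta <- config$obs_meta
  subjects <- sort(unique(meta$subject))
  sel <- function(g, ch) {
    keep <- meta$sign_channel == ch & meta$condition != "fixation"
    for (nm in names(g)) keep <- keep & meta[[nm]] == g[[nm]]
    keep
  }
  clipped <- FALSE
  fisher_z <- function(r) {
    if (any(r > 1 - 1e-7)) clipped <<- TRUE
    atanh(pmin(r, 1 - 1e-7))
  }
  out <- do.call(rbind, lapply(c("pos", "neg"), function(ch) {
    ka <- sel(grouping_a, ch); kb <- sel(grouping_b, ch)
    # per-subject mean edge weight per group: E x n_subjects
    Za <- vapply(subjects, function(s)
      fisher_z(rowMeans(config$mat[, ka & meta$subject == s, drop = FALSE])),
      numeric(nrow(config$mat)))
    Zb <- vapply(subjects, function(s)
      fisher_z(rowMeans(config$mat[, kb & meta$subject == s, drop = FALSE])),
      numeric(nrow(config$mat)))
    D <- Za - Zb
    md <- rowMeans(D)
    sdv <- apply(D, 1, stats::sd)
    n <- length(subjects)
    stat <- ifelse(sdv == 0, ifelse(md == 0, 0, sign(md) * Inf),
                   md / (sdv / sqrt(n)))
    p <- ifelse(sdv == 0, ifelse(md == 0, 1, 0),
                2 * stats::pt(-abs(stat), df = n - 1))
    data.frame(i = config$edge_index$i, j = config$edge_index$j,
               sign_channel = ch, mean_dz = md, statistic = stat, p = p,
               p_adj = stats::p.adjust(p, method = "BH"))
  }))
  if (clipped) warning("correlation magnitudes clipped at 1 - 1e-7")
  out$significant <- out$p_adj < fdr_q
  rownames(out) <- NULL
  out
}
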