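# From annotated regional time series to signed block networks and the
# normalized edge-configuration matrix consumed by the factorization.

#' Extract annotated block windows from a regional time series
#'
#' Each annotated block yields its full annotated length of samples starting
#' at `onset + shift_samples`. The default 4-sample shift aligns windows with
#' the canonical hemodynamic lag (6 s at a 1.5 s sampling interval).
#'
#' @param series A `regional_ts` (see [generate_bold()]) or a list with
#'   `values` (regions x samples) and `annotations` (columns subject, task,
#'   condition, block, onset_sample, n_samples).
#' @param shift_samples Non-negative window shift in samples (default 4).
#' @return A list of segments; each has `data` (regions x n_samples) and the
#'   annotation row as `meta`.
#' @export
extract_blocks <- function(series, shift_samples = 4L) {
  if (shift_samples < 0) stop("shift_samples must be >= 0")
  ann <- series$annotations
  total <- ncol(series$values)
  lapply(seq_len(nrow(ann)), function(r) {
    a <- ann$onset_sample[r] + shift_samples
    b <- a + ann$n_samples[r] - 1L
    if (b > total)
      stop(sprintf("shifted window [%d, %d] exceeds series length %d (block %d)",
                   a, b, total, r))
    list(data = series$values[, a:b, drop = FALSE], meta = ann[r, ])
  })
}

#' Pearson correlation matrix of one block segment
#'
#' @param segment Regions x samples matrix (or a segment from
#'   [extract_blocks()]).
#' @return Symmetric correlation matrix with unit diagonal. Regions with
#'   constant signal produce zero-weight edges (with a warning) rather than
#'   NaNs.
#' @export
block_correlation <- function(segment) {
  X <- if (is.list(segment)) segment$data else segment
  stopifnot(is.matrix(X))
  if (ncol(X) < 3) stop("need at least 3 samples per block")
  sds <- apply(X, 1, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warning(sprintf("%d region(s) with constant signal; their edges set to 0",
                    sum(flat)))
    X[flat, ] <- X[flat, ] + stats::rnorm(sum(flat) * ncol(X)) * 0  # keep dims
  }
  C <- suppressWarnings(stats::cor(t(X)))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  (C + t(C)) / 2
}

#' Split a correlation matrix into sign channels
#'
#' Thresholds at zero: the positive channel keeps entries `> 0`, the negative
#' channel keeps magnitudes of entries `< 0`. Off-diagonal, `pos - neg`
#' reconstructs the input exactly. Diagonals are zeroed.
#'
#' @param C Symmetric matrix.
#' @return List with non-negative matrices `pos` and `neg`.
#' @export
sign_split <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  pos <- pmax(C, 0)
  neg <- pmax(-C, 0)
  diag(pos) <- 0
  diag(neg) <- 0
  list(pos = pos, neg = neg)
}

#' Assemble the edge-configuration matrix
#'
#' Stacks the vectorized upper triangles of every (subject, task, condition,
#' block, sign channel) network into an E x T non-negative matrix with
#' E = N(N-1)/2 edges as rows and T observations as columns, columns ordered
#' lexicographically by (subject, task, condition, block, sign_channel).
#'
#' @param series_list List of `regional_ts` objects (all subjects).
#' @param design The [generate_design()] object (defines the expected cells).
#' @param shift_samples Window shift passed to [extract_blocks()].
#' @return A `config_matrix`: list with `mat` (E x T), `edge_index`
#'   (see [edge_index()]), `obs_meta` (one row per column), `n_regions`,
#'   and `normalized = FALSE`.
#' @export
assemble_configuration <- function(series_list, design, shift_samples = 4L) {
  stopifnot(inherits(design, "study_design"))
  n <- design$n_regions
  E <- n * (n - 1L) / 2L
  ei <- edge_index(n)

  segs <- list(); metas <- list()
  for (series in series_list) {
    blocks <- extract_blocks(series, shift_samples)
    for (b in blocks) {
      sp <- sign_split(block_correlation(b$data))
      for (ch in c("pos", "neg")) {
        key <- length(segs) + 1L
        segs[[key]] <- vectorize_edges(sp[[ch]])
        m <- b$meta
        metas[[key]] <- data.frame(
          subject = m$subject, task = m$task, condition = m$condition,
          block = m$block, sign_channel = ch, stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, metas)
  # every design cell must be present for every subject, twice (sign channels)
  want <- design$cells[, c("subject", "task", "condition", "block")]
  have <- meta[meta$sign_channel == "pos",
               c("subject", "task", "condition", "block")]
  key <- function(d) paste(d$subject, d$task, d$condition, d$block)
  missing <- setdiff(key(want), key(have))
  if (length(missing) > 0)
    stop("missing design cell(s): ", paste(utils::head(missing, 5), collapse = "; "))

  mat <- do.call(cbind, segs)
  ord <- order_observations(meta)
  mat <- mat[, ord, drop = FALSE]
  meta <- meta[ord, ]
  rownames(meta) <- NULL
  structure(list(mat = mat, edge_index = ei, obs_meta = meta,
                 n_regions = n, normalized = FALSE),
            class = "config_matrix")
}

#' @export
print.config_matrix <- function(x, ...) {
  cat(sprintf("config_matrix: %d edges x %d observations (%d regions)%s\n",
              nrow(x$mat), ncol(x$mat), x$n_regions,
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Normalize a configuration matrix
#'
#' Two-step normalization: (1) each observation's edge weights (one column)
#' are divided by their sum so every observed graph has unit edge density;
#' (2) each edge's vector of values across one subject's observations is
#' scaled to unit Euclidean length, separately per subject. Edge vectors with
#' zero norm are left at zero (and counted in a message).
#'
#' @param config A `config_matrix` from [assemble_configuration()].
#' @return The normalized `config_matrix` (`normalized = TRUE`).
#' @export
normalize_configuration <- function(config) {
  stopifnot(inherits(config, "config_matrix"))
  mat <- config$mat
  if (any(mat < 0)) stop("configuration entries must be non-negative")
  cs <- colSums(mat)
  if (any(cs == 0)) stop("all-zero observation column(s): ",
                         paste(utils::head(which(cs == 0), 5), collapse = ", "))
  mat <- sweep(mat, 2, cs, "/")
  n_zero <- 0L
  for (s in unique(config$obs_meta$subject)) {
    cols <- which(config$obs_meta$subject == s)
    nrm <- sqrt(rowSums(mat[, cols, drop = FALSE]^2))
    zero <- nrm == 0
    n_zero <- n_zero + sum(zero)
    nrm[zero] <- 1
    mat[, cols] <- mat[, cols, drop = FALSE] / nrm
  }
  if (n_zero > 0)
    message(sprintf("%d zero-norm edge vector(s) left at zero", n_zero))
  config$mat <- mat
  config$normalized <- TRUE
  config
}

#' Mean edge strength summaries with paired tests
#'
#' Computes per-subject mean edge weights under a grouping of the
#' configuration-matrix columns, and the associated paired t-test (two
#' groups) or one-way ANOVA across subjects (`grouping = "subject"`).
#'
#' Groupings: `"task"` (task blocks of each task), `"condition"` (low vs high
#' demand), `"fixation_vs_task"`, `"sign_channel"` (positive vs
#' negative-magnitude weights), `"subject"` (edge-weight distributions across
#' subjects, one-way ANOVA).
#'
#' @param config A `config_matrix`.
#' @param grouping One of the groupings above.
#' @return List with `means` (per subject x group) and `test` (data.frame
#'   with statistic, df, p.value, method).
#' @export
summarize_edge_strength <- function(config,
                                    grouping = c("task", "condition",
                                                 "fixation_vs_task",
                                                 "sign_channel", "subject")) {
  grouping <- match.arg(grouping)
  meta <- config$obs_meta
  mat <- config$mat
  subjects <- sort(unique(meta$subject))

  group_of <- switch(grouping,
    task = ifelse(meta$condition == "fixation", NA, meta$task),
    condition = ifelse(meta$condition %in% c("low", "high"),
                       as.character(meta$condition), NA),
    fixation_vs_task = ifelse(meta$condition == "fixation",
                              "fixation", "task"),
    sign_channel = as.character(meta$sign_channel),
    subject = as.character(meta$subject))

  if (grouping == "subject") {
    # edge-weight distribution comparison across subjects: one-way ANOVA on
    # per-observation mean weights grouped by subject
    obs_means <- colMeans(mat)
    fit <- stats::oneway.test(obs_means ~ factor(meta$subject),
                              var.equal = TRUE)
    means <- data.frame(subject = subjects,
                        mean_weight = tapply(obs_means, meta$subject, mean))
    test <- data.frame(statistic = unname(fit$statistic),
                       df = unname(fit$parameter[1]),
                       p.value = fit$p.value,
                       method = "one-way ANOVA")
    return(list(means = means, test = test))
  }

  keep <- !is.na(group_of)
  levs <- sort(unique(group_of[keep]))
  if (length(levs) != 2)
    stop("grouping must yield exactly two levels, got: ",
         paste(levs, collapse = ", "))
  per <- sapply(levs, function(g) {
    vapply(subjects, function(s) {
      cols <- which(keep & group_of == g & meta$subject == s)
      mean(mat[, cols])
    }, numeric(1))
  })
  means <- data.frame(subject = subjects, per)
  names(means)[-1] <- levs
  if (length(subjects) < 2)
    stop("paired test needs at least 2 subjects")
  tt <- paired_t(per[, 1], per[, 2])
  test <- data.frame(statistic = tt$statistic, df = tt$df, p.value = tt$p.value,
                     method = sprintf("paired t (%s - %s)", levs[1], levs[2]))
  list(means = means, test = test)
}
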