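# Synthetic cohort generator: a stated stand-in for an undeposited fMRI
# study. Plants low-rank signed covariance structure (community-aligned
# rank-1 subgraphs) in block-wise multivariate time series and couples
# reaction times to planted subgraph expression.

#' Enumerate a block-design study
#'
#' Builds the study design table: every (subject, task, condition, block)
#' cell exactly once. Defaults mirror a two-task, three-condition (fixation /
#' low / high demand), six-block cohort of 28 subjects measured over 262
#' regions grouped into 9 systems, 20 samples per block.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param tasks Character vector of task labels.
#' @param conditions Character vector of condition labels (shared by tasks).
#' @param blocks_per_condition Number of repeated blocks per condition.
#' @param samples_per_block Samples recorded per block.
#' @param n_regions Number of regions (network nodes).
#' @param n_systems Number of systems in the node partition
#'   (`n_systems <= n_regions`).
#' @param seed Integer master seed; all downstream randomness derives from it.
#' @return An object of class `study_design`: a list with the design scalars
#'   and a `cells` data.frame enumerating every design cell with its onset
#'   sample in the concatenated per-subject series.
#' @export
#' @examples
#' d <- generate_design(n_subjects = 2, seed = 1)
#' nrow(d$cells) / 2  # 36 block cells per subject
generate_design <- function(n_subjects = 28L,
                            tasks = c("stroop", "navon"),
                            conditions = c("fixation", "low", "high"),
                            blocks_per_condition = 6L,
                            samples_per_block = 20L,
                            n_regions = 262L,
                            n_systems = 9L,
                            seed = 1L) {
  counts <- c(n_subjects, blocks_per_condition, samples_per_block,
              n_regions, n_systems, length(tasks), length(conditions))
  if (any(counts < 1)) stop("all design counts must be >= 1")
  if (n_systems > n_regions) stop("n_systems must not exceed n_regions")
  cells <- expand.grid(
    block = seq_len(blocks_per_condition),
    condition = conditions,
    task = tasks,
    subject = seq_len(n_subjects),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("subject", "task", "condition", "block")]
  cells <- cells[order(cells$subject, cells$task,
                       match(cells$condition, conditions), cells$block), ]
  rownames(cells) <- NULL
  # blocks are laid out consecutively within each subject's series, with a
  # trailing pad so a shifted analysis window stays in bounds
  per_subj <- nrow(cells) / n_subjects
  cells$onset_sample <- ((seq_len(nrow(cells)) - 1L) %% per_subj) *
    samples_per_block + 1L
  cells$n_samples <- samples_per_block
  structure(list(
    n_subjects = as.integer(n_subjects), tasks = tasks,
    conditions = conditions,
    blocks_per_condition = as.integer(blocks_per_condition),
    samples_per_block = as.integer(samples_per_block),
    n_regions = as.integer(n_regions), n_systems = as.integer(n_systems),
    seed = as.integer(seed), cells = cells
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "study_design: %d subjects x %d tasks x %d conditions x %d blocks (%d samples/block), %d regions / %d systems\n",
    x$n_subjects, length(x$tasks), length(x$conditions),
    x$blocks_per_condition, x$samples_per_block, x$n_regions, x$n_systems))
  invisible(x)
}

#' Plant ground-truth subgraphs, expression, and behavior coupling
#'
#' Builds `n_subgraphs` rank-1 community subgraphs, a non-negative expression
#' coefficient per subgraph per design observation and sign channel, and a
#' per-subgraph coefficient linking expression to reaction-time cost.
#'
#' Half of the subgraphs (rounded up) are positive-dominant, the rest
#' negative-dominant. A positive-dominant subgraph is a rank-1 community
#' block over the nodes of two systems of the partition (node loadings
#' uniform on \[0.4, 0.8\]): its edges surface as correlated dynamics in the
#' positive sign channel. A negative-dominant subgraph is two disjoint
#' matchings of anticorrelated node pairs between one system pair (pair
#' weights uniform on \[0.5, 0.7\], node degree at most two): each pair
#' fluctuates in genuine opposition, so its edges surface as strong
#' anticorrelations in the negative channel. Pair constructions avoid
#' the positive "shadow" correlations that a rank-1 anti-phase block would
#' inevitably produce, keeping every planted subgraph's edges in a single
#' coherent channel; block-wise anticorrelation planted by *subtracting*
#' subgraph mass is instead capped at ~1/(block size - 1) by positive
#' definiteness, which is why it is not used here. `structure = "random"`
#' places blocks/pairs on random node subsets (for independence nulls).
#'
#' A single non-negative driver `h_k(cell)` (uniform on `expression_range`
#' times a subject gain on \[0.7, 1.3\]) expresses subgraph `k` in each design
#' cell: the covariance of that cell gains `h_k P_k` where `P_k` is the
#' subgraph's signed pattern. The recorded channel coefficients split the
#' driver by the pattern's signed edge-mass fractions, so relative expression
#' (positive minus negative) co-fluctuates with the driver and has the
#' dominant sign. Fixation cells express at half strength.
#'
#' @param design A [generate_design()] object.
#' @param n_subgraphs Number of planted subgraphs.
#' @param expression_range Range of the per-cell expression driver; the
#'   default spans the full \[0, 1\] interval because subgraph detectability
#'   rests on expression genuinely co-fluctuating across observations.
#' @param behavior_effect Numeric vector (length `n_subgraphs`, recycled) of
#'   ms-per-unit-expression couplings between a subject's planted relative
#'   expression and reaction-time cost.
#' @param noise_sd Baseline (identity) standard deviation of the regional
#'   signal; must be positive.
#' @param structure `"system"` (partition-aligned blocks/pairs) or
#'   `"random"`.
#' @return An object of class `ground_truth` with elements `subgraphs`
#'   (list of symmetric zero-diagonal non-negative matrices `|P_k|`),
#'   `patterns` (the signed symmetric patterns `P_k`), `expression` (array
#'   subgraph x observation-cell x channel, channels `pos`/`neg`),
#'   `dominant`, `partition` (a `system_partition`), `behavior_effect`,
#'   `noise_sd`.
#' @export
generate_truth <- function(design, n_subgraphs = 4L,
                           expression_range = c(0, 1),
                           behavior_effect = 0,
                           noise_sd = 1,
                           structure = c("system", "random")) {
  structure <- match.arg(structure)
  stopifnot(inherits(design, "study_design"), n_subgraphs >= 1)
  if (noise_sd <= 0) stop("noise_sd must be positive")
  n <- design$n_regions
  part <- synthetic_partition(n, design$n_systems)
  seeds <- derive_seeds(design$seed, 2L, salt = 11L)
  dominant <- rep(c("pos", "neg"), length.out = n_subgraphs)

  patterns <- with_seed(seeds[1], {
    sys_counter <- 0L
    claim_systems <- function(n_claim) {
      # round-robin over systems so planted subgraphs stay edge-disjoint
      sys <- (sys_counter + seq_len(n_claim) - 1L) %% design$n_systems + 1L
      sys_counter <<- sys_counter + n_claim
      lapply(sys, function(s)
        which(part$assignment == levels(part$assignment)[s]))
    }
    # negative-dominant subgraphs claim systems first (they get the larger
    # systems of the partition: anticorrelation carries less weight per edge,
    # so they need the extra pairs)
    build_neg <- function() {
      P <- matrix(0, n, n)
      groups <- if (structure == "system") claim_systems(2L)
                else {
                  pool <- sample.int(n, 2L * max(4L, round(n / (2 * max(2, n_subgraphs)))))
                  split(pool, rep(1:2, length.out = length(pool)))
                }
      # two disjoint matchings between the system pair (node degree <= 2)
      a <- groups[[1]]; b <- groups[[2]]
      np <- min(length(a), length(b))
      for (shift in 0:1) {
        bb <- b[(seq_len(np) + shift - 1L) %% np + 1L]
        wts <- runif(np, 0.5, 0.7)
        P[cbind(a[seq_len(np)], bb)] <- -wts
        P[cbind(bb, a[seq_len(np)])] <- -wts
      }
      # spectral normalization: h * lambda_max(P) must stay < 1 at the
      # largest driver, or the sampler's eigenvalue floor would
      # erase the planted anticorrelation exactly in the strongest cells
      lam <- max(abs(eigen(P, symmetric = TRUE, only.values = TRUE)$values))
      P * (0.95 / lam)
    }
    build_pos <- function() {
      nodes <- if (structure == "system") unlist(claim_systems(2L))
               else sample.int(n, max(6L, round(n / max(2, n_subgraphs))))
      u <- numeric(n)
      u[nodes] <- runif(length(nodes), 0.4, 0.8)
      P <- tcrossprod(u)
      diag(P) <- 0
      P
    }
    built <- list()
    for (k in order(dominant == "pos")) # neg first
      built[[k]] <- if (dominant[k] == "neg") build_neg() else build_pos()
    built
  })
  subgraphs <- lapply(patterns, function(P) abs(P))
  # share of each subgraph's edge mass surfacing in each sign channel
  channel_frac <- vapply(patterns, function(P) {
    tot <- sum(abs(P))
    c(pos = sum(P[P > 0]) / tot, neg = sum(-P[P < 0]) / tot)
  }, numeric(2))

  cells <- design$cells
  n_cells <- nrow(cells)
  expr <- with_seed(seeds[2], {
    e <- array(0, dim = c(n_subgraphs, n_cells, 2L),
               dimnames = list(NULL, NULL, c("pos", "neg")))
    for (k in seq_len(n_subgraphs)) {
      h <- runif(n_cells, expression_range[1], expression_range[2])
      gain <- runif(design$n_subjects, 0.85, 1.15)[cells$subject]
      # task preference (rotating): subgraphs are expressed strongly during
      # their preferred task and weakly otherwise, mirroring task-specific
      # subgraph recruitment; this is also what renders same-channel
      # subgraphs temporally separable
      pref <- design$tasks[(ceiling(k / 2) - 1L) %% length(design$tasks) + 1L]
      task_mod <- ifelse(cells$task == pref, 1, 0.25)
      # alternating demand tilt: odd subgraphs lean low-demand, even lean
      # high-demand (gives condition contrasts a planted effect)
      pref_cond <- if (k %% 2 == 1) "low" else "high"
      cond_mod <- ifelse(cells$condition == pref_cond, 1, 0.6)
      h <- h * gain * task_mod * cond_mod
      e[k, , "pos"] <- h * channel_frac["pos", k]
      e[k, , "neg"] <- h * channel_frac["neg", k]
    }
    fix <- cells$condition == "fixation"
    e[, fix, ] <- e[, fix, ] * 0.5
    e
  })

  structure(list(
    subgraphs = subgraphs,
    patterns = patterns,
    expression = expr,
    dominant = dominant,
    partition = part,
    behavior_effect = rep_len(behavior_effect, n_subgraphs),
    noise_sd = noise_sd,
    structure = structure
  ), class = "ground_truth")
}

#' Synthetic node-to-system partition
#'
#' Splits `n_regions` into `n_systems` contiguous, near-equal systems labelled
#' `S1..Sk`.
#'
#' @param n_regions Number of regions.
#' @param n_systems Number of systems.
#' @return A `system_partition`: list with `assignment` (factor of length
#'   `n_regions`) and `systems` (levels).
#' @export
synthetic_partition <- function(n_regions, n_systems) {
  stopifnot(n_systems >= 1, n_systems <= n_regions)
  labs <- sprintf("S%d", seq_len(n_systems))
  sizes <- rep(n_regions %/% n_systems, n_systems)
  extra <- n_regions %% n_systems
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assignment <- factor(rep(labs, times = sizes), levels = labs)
  structure(list(assignment = assignment, systems = labs),
            class = "system_partition")
}

#' Build a system partition from a two-column table
#'
#' @param region_id Integer region ids 1..N (any order, each exactly once).
#' @param system_label System label per region.
#' @return A `system_partition`.
#' @export
system_partition <- function(region_id, system_label) {
  n <- length(region_id)
  if (!setequal(region_id, seq_len(n)))
    stop("region_id must cover 1..N exactly once")
  assignment <- factor(system_label[order(region_id)])
  structure(list(assignment = assignment, systems = levels(assignment)),
            class = "system_partition")
}

# Assemble the planted block covariance for one design cell:
# identity * noise_sd^2 plus driver-weighted signed zero-diagonal patterns
# h_k P_k. Under unit noise the implied correlation of a planted edge is
# h * P_ij. Mild indefiniteness at high drivers is handled by the sampler's
# 1e-6 eigenvalue floor.
planted_covariance <- function(truth, cell_idx) {
  n <- nrow(truth$subgraphs[[1]])
  S <- diag(truth$noise_sd^2, n)
  for (k in seq_along(truth$subgraphs)) {
    driver <- truth$expression[k, cell_idx, "pos"] +
      truth$expression[k, cell_idx, "neg"]
    S <- S + driver * truth$patterns[[k]]
  }
  (S + t(S)) / 2
}

# Sample nsamp rows from N(0, S); floors eigenvalues at 1e-6 when the
# Cholesky factorization fails.
rmvn_floor <- function(nsamp, S) {
  n <- nrow(S)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    es <- eigen(S, symmetric = TRUE)
    lam <- pmax(es$values, 1e-6)
    R <- t(es$vectors %*% (t(es$vectors) * sqrt(lam)))
    # R is not triangular here; treat as a general square root factor
    Z <- matrix(stats::rnorm(nsamp * n), nsamp, n)
    return(Z %*% R)
  }
  Z <- matrix(stats::rnorm(nsamp * n), nsamp, n)
  Z %*% R
}

#' Generate regional time series for every subject
#'
#' For each design cell, samples are drawn from a zero-mean multivariate
#' normal whose covariance is the identity (scaled by `noise_sd^2`) plus the
#' net-expression-weighted sum of planted subgraph matrices
#' (negative-channel expression subtracts), symmetrized and
#' eigenvalue-floored at 1e-6 when needed. One RNG stream per subject derives
#' from the design master seed.
#'
#' @param design A [generate_design()] object.
#' @param truth A [generate_truth()] object sized to the design.
#' @param lag_samples Hemodynamic lag emulated by the generator: block r's
#'   covariance-pure samples occupy `[onset + lag, onset + lag + n_samples)`,
#'   so [extract_blocks()] with the default 4-TR shift recovers them exactly
#'   (default 4).
#' @return A list of `regional_ts` objects (one per subject), each with
#'   `subject_id`, `values` (regions x samples), `sampling_interval` (1.5 s)
#'   and `annotations` (the subject's design cells).
#' @export
generate_bold <- function(design, truth, lag_samples = 4L) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "ground_truth"))
  if (nrow(truth$subgraphs[[1]]) != design$n_regions)
    stop("truth matrices are not sized to design$n_regions")
  cells <- design$cells
  seeds <- derive_seeds(design$seed, design$n_subjects, salt = 23L)
  lapply(seq_len(design$n_subjects), function(s) {
    rows <- which(cells$subject == s)
    ann <- cells[rows, ]
    rownames(ann) <- NULL
    total <- max(ann$onset_sample + ann$n_samples - 1L) + lag_samples
    vals <- NULL
    with_seed(seeds[s], {
      # baseline noise fills inter-block lag gaps
      vals <- matrix(stats::rnorm(design$n_regions * total,
                                  sd = truth$noise_sd),
                     design$n_regions, total)
      for (r in rows) {
        S <- planted_covariance(truth, r)
        x <- rmvn_floor(cells$n_samples[r], S)
        a <- cells$onset_sample[r] + lag_samples
        vals[, a:(a + cells$n_samples[r] - 1L)] <- t(x)
      }
    })
    structure(list(subject_id = s, values = vals, sampling_interval = 1.5,
                   annotations = ann),
              class = "regional_ts")
  })
}

#' Generate a per-trial behavior table
#'
#' Reaction times on task (non-fixation) blocks are drawn as
#' `baseline + offset * [condition == high] + sum_k effect_k * relative
#' expression_k + noise`, 20 trials per block, with a Bernoulli correctness
#' flag. Relative expression is the subject's planted positive-minus-negative
#' channel expression for that cell.
#'
#' @param design A [generate_design()] object.
#' @param truth A [generate_truth()] object.
#' @param baseline_ms Mean reaction time in the low-demand condition (> 0).
#' @param demand_offset_ms Added mean reaction time under high demand.
#' @param rt_noise_sd Trial-level reaction-time noise (ms).
#' @param trials_per_block Trials per task block (default 20).
#' @param p_correct Probability a trial is correct.
#' @return A `behavior_table` data.frame with columns subject, task,
#'   condition, block, trial, rt_ms, correct.
#' @export
generate_behavior <- function(design, truth,
                              baseline_ms = 600,
                              demand_offset_ms = 120,
                              rt_noise_sd = 60,
                              trials_per_block = 20L,
                              p_correct = 0.96) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "ground_truth"))
  if (baseline_ms <= 0) stop("baseline_ms must be positive")
  cells <- design$cells
  task_rows <- which(cells$condition != "fixation")
  seeds <- derive_seeds(design$seed, 1L, salt = 37L)
  nk <- length(truth$subgraphs)
  relexp <- vapply(seq_len(nrow(cells)), function(r) {
    sum(truth$behavior_effect *
          (truth$expression[, r, "pos"] - truth$expression[, r, "neg"]))
  }, numeric(1))
  with_seed(seeds[1], {
    out <- do.call(rbind, lapply(task_rows, function(r) {
      mu <- baseline_ms +
        ifelse(cells$condition[r] == "high", demand_offset_ms, 0) + relexp[r]
      rt <- stats::rnorm(trials_per_block, mu, rt_noise_sd)
      rt <- pmax(rt, 150)  # physiological floor
      data.frame(subject = cells$subject[r], task = cells$task[r],
                 condition = cells$condition[r], block = cells$block[r],
                 trial = seq_len(trials_per_block), rt_ms = rt,
                 correct = as.integer(stats::runif(trials_per_block) <= p_correct))
    }))
    class(out) <- c("behavior_table", "data.frame")
    out
  })
}

#' Planted expression summary on the pipeline's observation grid
#'
#' Returns the generator's ground-truth expression arranged like an
#' [relative_expression()] summary (per subject x subgraph x task x condition
#' x block), for oracle comparisons and behavior-linkage tests.
#'
#' @param design A [generate_design()] object.
#' @param truth A [generate_truth()] object.
#' @return A data.frame with columns subject, task, condition, block,
#'   subgraph, positive, negative, relative.
#' @export
planted_expression_summary <- function(design, truth) {
  cells <- design$cells
  nk <- length(truth$subgraphs)
  out <- do.call(rbind, lapply(seq_len(nk), function(k) {
    data.frame(subject = cells$subject, task = cells$task,
               condition = cells$condition, block = cells$block,
               subgraph = k,
               positive = truth$expression[k, , "pos"],
               negative = truth$expression[k, , "neg"])
  }))
  out$relative <- out$positive - out$negative
  out
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: design, truth, time series, behavior.
#'
#' @inheritParams generate_design
#' @inheritParams generate_truth
#' @param ... Passed on to [generate_truth()].
#' @return List with `design`, `truth`, `series` (list of `regional_ts`) and
#'   `behavior`.
#' @export
simulate_cohort <- function(n_subjects = 28L, n_regions = 262L,
                            n_subgraphs = 4L, seed = 1L, ...) {
  design <- generate_design(n_subjects = n_subjects, n_regions = n_regions,
                            seed = seed)
  truth <- generate_truth(design, n_subgraphs = n_subgraphs, ...)
  series <- generate_bold(design, truth)
  behavior <- generate_behavior(design, truth)
  list(design = design, truth = truth, series = series, behavior = behavior)
}
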