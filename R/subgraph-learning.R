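# Regularized NMF of the configuration matrix:
#   min_{W,H >= 0} 1/2 ||A - WH||_F^2 + alpha ||W||_F^2
#                  + beta sum_t ||H(:,t)||_1^2
# solved by alternating non-negative least squares with block principal
# pivoting, plus random-sampling cross-validated model selection and
# consensus clustering over repeated runs.

#' NMF parameter set
#'
#' @param m Number of subgraphs (>= 1; rank-1 fits are allowed for testing,
#'   analyses use m >= 2).
#' @param beta Expression-sparsity penalty (squared L1 of each column of H).
#' @param alpha Subgraph regularization (squared Frobenius norm of W).
#' @param max_iter Iteration cap of the alternating solver (default 100).
#' @param tol Relative objective-change convergence tolerance (default 1e-6).
#' @param seed Integer seed for the uniform \[0, 1\] initialization.
#' @return An `nmf_params` list.
#' @export
nmf_params <- function(m, beta = 0, alpha = 0, max_iter = 100L,
                       tol = 1e-6, seed = 1L) {
  if (m < 1) stop("m must be >= 1")
  if (beta < 0 || alpha < 0) stop("beta and alpha must be >= 0")
  structure(list(m = as.integer(m), beta = beta, alpha = alpha,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "nmf_params")
}

#' Regularized NMF objective
#'
#' `1/2 ||A - WH||_F^2 + alpha ||W||_F^2 + beta sum_t (sum_k H[k,t])^2`.
#'
#' @param A E x T non-negative data matrix.
#' @param W E x m non-negative subgraph matrix.
#' @param H m x T non-negative expression matrix.
#' @param alpha,beta Non-negative penalty weights.
#' @return The scalar objective value.
#' @export
nmf_objective <- function(A, W, H, alpha = 0, beta = 0) {
  if (any(A < 0) || any(W < 0) || any(H < 0))
    stop("A, W, H must be non-negative")
  R <- A - W %*% H
  0.5 * sum(R^2) + alpha * sum(W^2) + beta * sum(colSums(H)^2)
}

# One exact H-subproblem solve: min_H 1/2||A-WH||^2 + beta sum_t ||H(:,t)||_1^2
# via augmentation: beta * (1'h)^2 = ||sqrt(2*beta) 1' h||^2 / 2.
solve_H <- function(A, W, beta) {
  m <- ncol(W)
  CtC <- crossprod(W) + 2 * beta * matrix(1, m, m)
  nnls_bpp(CtC, crossprod(W, A))
}

# One exact W-subproblem solve: min_W 1/2||A-WH||^2 + alpha ||W||^2.
solve_W <- function(A, H, alpha) {
  m <- nrow(H)
  CtC <- tcrossprod(H) + diag(2 * alpha, m)
  t(nnls_bpp(CtC, H %*% t(A)))
}

#' Fit the regularized NMF by alternating NNLS (block pivoting)
#'
#' W and H are initialized uniform on \[0, 1\] from `params$seed`; each
#' alternation solves both regularized subproblems exactly, so the objective
#' trace is monotone non-increasing. Stops at `max_iter` (default 100) or
#' when the relative objective change drops below `tol`.
#'
#' @param A E x T non-negative matrix (a `config_matrix` or plain matrix).
#' @param params An [nmf_params()] object.
#' @return A `subgraph_decomp`: list with `W` (E x m), `H` (m x T),
#'   `objective_trace`, `params`, and (when `A` is a `config_matrix`)
#'   `edge_index` / `obs_meta`.
#' @export
fit_nmf <- function(A, params) {
  cfg <- NULL
  if (inherits(A, "config_matrix")) { cfg <- A; A <- A$mat }
  stopifnot(is.matrix(A))
  if (any(!is.finite(A))) stop("A contains non-finite entries")
  if (any(A < 0)) stop("A must be non-negative")
  m <- params$m
  if (m >= min(dim(A)))
    stop(sprintf("m = %d must be < min(E, T) = %d", m, min(dim(A))))
  E <- nrow(A); Tn <- ncol(A)
  init <- with_seed(params$seed, list(
    W = matrix(stats::runif(E * m), E, m),
    H = matrix(stats::runif(m * Tn), m, Tn)))
  W <- init$W; H <- init$H
  trace <- numeric(0)
  obj_prev <- Inf
  for (it in seq_len(params$max_iter)) {
    H <- solve_H(A, W, params$beta)
    W <- solve_W(A, H, params$alpha)
    obj <- nmf_objective(A, W, H, params$alpha, params$beta)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= params$tol * max(obj_prev, .Machine$double.eps))
      break
    obj_prev <- obj
  }
  out <- list(W = W, H = H, objective_trace = trace, params = params)
  if (!is.null(cfg)) {
    out$edge_index <- cfg$edge_index
    out$obs_meta <- cfg$obs_meta
  }
  structure(out, class = "subgraph_decomp")
}

#' @export
print.subgraph_decomp <- function(x, ...) {
  cat(sprintf(
    "subgraph_decomp: %d edges x %d subgraphs x %d observations; final objective %.6g after %d iterations\n",
    nrow(x$W), ncol(x$W), ncol(x$H),
    utils::tail(x$objective_trace, 1), length(x$objective_trace)))
  invisible(x)
}

#' Fit expression coefficients for a fixed subgraph matrix
#'
#' Solves the H-subproblem of the regularized objective with W frozen
#' (per-column non-negative least squares plus the beta penalty). Used for
#' held-out cross-validation error and consensus expression coefficients.
#' All-zero columns of `W_fixed` get zero coefficients (with a message).
#'
#' @param A E x T non-negative matrix (or `config_matrix`).
#' @param W_fixed E x m non-negative subgraph matrix.
#' @param beta Expression-sparsity penalty.
#' @return m x T non-negative expression matrix.
#' @export
fit_expression <- function(A, W_fixed, beta = 0) {
  if (inherits(A, "config_matrix")) A <- A$mat
  stopifnot(is.matrix(W_fixed), nrow(W_fixed) == nrow(A))
  if (any(W_fixed < 0)) stop("W_fixed must be non-negative")
  dead <- colSums(W_fixed) == 0
  if (any(dead)) {
    message(sprintf("%d zero subgraph column(s); coefficients set to 0",
                    sum(dead)))
    W_live <- W_fixed[, !dead, drop = FALSE]
    H <- matrix(0, ncol(W_fixed), ncol(A))
    if (ncol(W_live) > 0) H[!dead, ] <- solve_H(A, W_live, beta)
    return(H)
  }
  solve_H(A, W_fixed, beta)
}

#' Random parameter sampling for model selection
#'
#' Draws `n_samples` parameter sets with `m` integer-uniform and `beta`,
#' `alpha` continuous-uniform on their ranges (defaults: m in \[3, 50\],
#' beta and alpha in \[0.01, 5\]).
#'
#' @param n_samples Number of sets (>= 1; the reference scheme uses 1000).
#' @param m_range,beta_range,alpha_range Sampling ranges.
#' @param seed Integer seed.
#' @return List of [nmf_params()], each carrying its own derived seed.
#' @export
sample_parameters <- function(n_samples, m_range = c(3L, 50L),
                              beta_range = c(0.01, 5),
                              alpha_range = c(0.01, 5),
                              seed = 1L) {
  stopifnot(n_samples >= 1)
  if (m_range[1] > m_range[2] || beta_range[1] > beta_range[2] ||
      alpha_range[1] > alpha_range[2]) stop("empty range")
  seeds <- derive_seeds(seed, n_samples, salt = 41L)
  with_seed(seed, {
    m_vals <- seq.int(m_range[1], m_range[2])
    ms <- m_vals[sample.int(length(m_vals), n_samples, replace = TRUE)]
    betas <- stats::runif(n_samples, beta_range[1], beta_range[2])
    alphas <- stats::runif(n_samples, alpha_range[1], alpha_range[2])
    lapply(seq_len(n_samples), function(i)
      nmf_params(m = ms[i], beta = betas[i], alpha = alphas[i],
                 seed = seeds[i]))
  })
}

#' Subject-level k-fold cross-validation of NMF parameters
#'
#' Subjects are partitioned uniformly into `n_folds` folds; for each sampled
#' parameter set and fold, subgraphs are fit on the training subjects'
#' columns and the held-out error `||A_held - W H_held||_F^2` is computed
#' with expression refit via [fit_expression()]. Errors are averaged over
#' folds.
#'
#' @param config A normalized `config_matrix`.
#' @param param_sets List of [nmf_params()] (e.g. from [sample_parameters()]).
#' @param n_folds Number of folds (default 4).
#' @param seed Seed for the fold assignment.
#' @return A `cv_result`: data.frame `errors` (m, beta, alpha, cv_error) plus
#'   `folds` (subject -> fold).
#' @export
cross_validate <- function(config, param_sets, n_folds = 4L, seed = 1L) {
  stopifnot(inherits(config, "config_matrix"))
  subjects <- sort(unique(config$obs_meta$subject))
  if (n_folds > length(subjects)) stop("more folds than subjects")
  fold_of <- with_seed(seed, {
    sizes <- rep(length(subjects) %/% n_folds, n_folds)
    extra <- length(subjects) %% n_folds
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    sample(rep(seq_len(n_folds), times = sizes))
  })
  names(fold_of) <- subjects
  if (any(table(fold_of) == 0)) stop("fold with zero subjects")

  errs <- vapply(param_sets, function(p) {
    fold_err <- vapply(seq_len(n_folds), function(f) {
      held <- subjects[fold_of == f]
      hcols <- config$obs_meta$subject %in% held
      A_tr <- config$mat[, !hcols, drop = FALSE]
      A_ho <- config$mat[, hcols, drop = FALSE]
      fit <- fit_nmf(A_tr, p)
      H_ho <- fit_expression(A_ho, fit$W, p$beta)
      sum((A_ho - fit$W %*% H_ho)^2)
    }, numeric(1))
    mean(fold_err)
  }, numeric(1))

  errors <- data.frame(
    m = vapply(param_sets, `[[`, integer(1), "m"),
    beta = vapply(param_sets, `[[`, numeric(1), "beta"),
    alpha = vapply(param_sets, `[[`, numeric(1), "alpha"),
    cv_error = errs)
  structure(list(errors = errors, folds = fold_of, n_folds = n_folds),
            class = "cv_result")
}

#' Select the optimum parameter set from cross-validation results
#'
#' Averages m (rounded half-up), beta, and alpha over all sampled sets whose
#' fold-averaged error is at or below the given percentile of the error
#' distribution (default: bottom 5%).
#'
#' @param cv_result A [cross_validate()] result.
#' @param percentile Percentile cutoff in (0, 100\].
#' @param seed Seed attached to the returned parameter set.
#' @return An [nmf_params()] object.
#' @export
select_optimum <- function(cv_result, percentile = 5, seed = 1L) {
  stopifnot(inherits(cv_result, "cv_result"))
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0, 100]")
  e <- cv_result$errors
  if (nrow(e) < 1) stop("no sampled parameter sets")
  cut <- stats::quantile(e$cv_error, percentile / 100, names = FALSE)
  sel <- e[e$cv_error <= cut, ]
  if (nrow(sel) == 0) stop("empty selection")
  nmf_params(m = floor(mean(sel$m) + 0.5),  # round half-up
             beta = mean(sel$beta), alpha = mean(sel$alpha), seed = seed)
}

#' Consensus subgraphs over repeated factorization runs
#'
#' Runs the factorization `R` times from different seeds, L2-normalizes each
#' run's subgraph columns, concatenates them into an E x (R*m) aggregate,
#' re-factorizes the aggregate at rank m, and refits expression against the
#' consensus subgraphs. Consensus subgraph columns are returned
#' L2-normalized.
#'
#' @param config A normalized `config_matrix` (or plain matrix).
#' @param params An [nmf_params()] object.
#' @param R Number of runs (>= 2; the reference scheme uses 1000).
#' @return A `consensus_result`: `W_consensus` (E x m, unit-L2 columns),
#'   `H_consensus` (m x T), `run_seeds`, `R`.
#' @export
consensus_cluster <- function(config, params, R = 100L) {
  A <- if (inherits(config, "config_matrix")) config$mat else config
  if (R < 2) stop("R must be >= 2")
  run_seeds <- derive_seeds(params$seed, R + 1L, salt = 53L)
  runs <- lapply(seq_len(R), function(r) {
    p <- params; p$seed <- run_seeds[r]
    fit <- tryCatch(fit_nmf(A, p),
                    error = function(e)
                      stop(sprintf("consensus run %d failed: %s", r,
                                   conditionMessage(e)), call. = FALSE))
    l2_normalize_cols(fit$W)
  })
  agg <- do.call(cbind, runs)
  p_agg <- params; p_agg$seed <- run_seeds[R + 1L]
  fit_agg <- fit_nmf(agg, p_agg)
  W_cons <- l2_normalize_cols(fit_agg$W)
  H_cons <- fit_expression(A, W_cons, params$beta)
  out <- list(W_consensus = W_cons, H_consensus = H_cons,
              run_seeds = run_seeds[seq_len(R)], R = R, params = params)
  if (inherits(config, "config_matrix")) {
    out$edge_index <- config$edge_index
    out$obs_meta <- config$obs_meta
  }
  structure(out, class = "consensus_result")
}

# L2-normalize matrix columns; zero columns stay zero.
l2_normalize_cols <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  sweep(M, 2, nrm, "/")
}
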