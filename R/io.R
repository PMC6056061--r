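# Plain-text (TSV) interchange: cohort exports, partition and behavior
# tables, and a directory-based decomposition container (an HDF5-free stand
# in; every array is a TSV, metadata is key-value TSV).

#' Write a synthetic cohort to TSV files
#'
#' Writes one `timeseries_sub<id>.tsv` per subject (regions x samples),
#' `blocks.tsv` (subject, task, condition, block, onset_sample, n_samples),
#' `partition.tsv` (region_id, system_label) and `behavior.tsv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ts in cohort$series) {
    utils::write.table(
      ts$values,
      file.path(dir, sprintf("timeseries_sub%03d.tsv", ts$subject_id)),
      sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(cohort$design$cells, file.path(dir, "blocks.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  part <- data.frame(region_id = seq_along(cohort$truth$partition$assignment),
                     system_label = as.character(cohort$truth$partition$assignment))
  utils::write.table(part, file.path(dir, "partition.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the TSV files.
#' @param sampling_interval Seconds per sample (default 1.5).
#' @return List with `series` (list of `regional_ts`), `partition`
#'   (a `system_partition`) and `behavior`.
#' @export
read_cohort <- function(dir, sampling_interval = 1.5) {
  blocks <- utils::read.delim(file.path(dir, "blocks.tsv"))
  part_tab <- utils::read.delim(file.path(dir, "partition.tsv"))
  behavior <- utils::read.delim(file.path(dir, "behavior.tsv"))
  files <- sort(list.files(dir, pattern = "^timeseries_sub\\d+\\.tsv$",
                           full.names = TRUE))
  series <- lapply(files, function(f) {
    sid <- as.integer(sub(".*sub(\\d+)\\.tsv$", "\\1", f))
    vals <- as.matrix(utils::read.delim(f, header = FALSE))
    dimnames(vals) <- NULL
    ann <- blocks[blocks$subject == sid, ]
    rownames(ann) <- NULL
    structure(list(subject_id = sid, values = vals,
                   sampling_interval = sampling_interval, annotations = ann),
              class = "regional_ts")
  })
  list(series = series,
       partition = system_partition(part_tab$region_id, part_tab$system_label),
       behavior = behavior)
}

#' Save a decomposition as a TSV container directory
#'
#' Writes `W.tsv`, `H.tsv`, `edge_index.tsv`, `obs_meta.tsv` and
#' `params.tsv` (key-value) into `dir`.
#'
#' @param decomp A `subgraph_decomp` or `consensus_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(decomp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  W <- as_W_matrix(decomp)
  H <- if (inherits(decomp, "consensus_result")) decomp$H_consensus else decomp$H
  utils::write.table(W, file.path(dir, "W.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(H, file.path(dir, "H.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(decomp$edge_index))
    utils::write.table(decomp$edge_index, file.path(dir, "edge_index.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(decomp$obs_meta))
    utils::write.table(decomp$obs_meta, file.path(dir, "obs_meta.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  p <- decomp$params
  kv <- data.frame(key = c("m", "beta", "alpha", "max_iter", "tol", "seed"),
                   value = c(p$m, p$beta, p$alpha, p$max_iter, p$tol, p$seed))
  if (inherits(decomp, "consensus_result")) {
    kv <- rbind(kv, data.frame(key = "R", value = decomp$R),
                data.frame(key = sprintf("run_seed_%d", seq_along(decomp$run_seeds)),
                           value = decomp$run_seeds))
  }
  utils::write.table(kv, file.path(dir, "params.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Load a decomposition container written by [write_decomposition()]
#'
#' @param dir Container directory.
#' @return A list with `W`, `H`, `edge_index`, `obs_meta`, `params`.
#' @export
read_decomposition <- function(dir) {
  W <- as.matrix(utils::read.delim(file.path(dir, "W.tsv"), header = FALSE))
  H <- as.matrix(utils::read.delim(file.path(dir, "H.tsv"), header = FALSE))
  dimnames(W) <- NULL; dimnames(H) <- NULL
  kv <- utils::read.delim(file.path(dir, "params.tsv"))
  params <- stats::setNames(as.list(kv$value), kv$key)
  out <- list(W = W, H = H, params = params)
  ef <- file.path(dir, "edge_index.tsv")
  if (file.exists(ef)) out$edge_index <- utils::read.delim(ef)
  mf <- file.path(dir, "obs_meta.tsv")
  if (file.exists(mf)) out$obs_meta <- utils::read.delim(mf)
  out
}

#' Build a configuration matrix from an on-disk cohort
#'
#' Convenience: read cohort TSVs, extract shifted blocks, correlate, sign
#' split, assemble and (optionally) normalize.
#'
#' @param dir Cohort directory (see [write_cohort()]).
#' @param design A [generate_design()] object describing the cohort.
#' @param shift_samples Window shift (default 4).
#' @param normalize Apply [normalize_configuration()] (default TRUE).
#' @return A `config_matrix`.
#' @export
configuration_from_dir <- function(dir, design, shift_samples = 4L,
                                   normalize = TRUE) {
  cohort <- read_cohort(dir)
  cfg <- assemble_configuration(cohort$series, design, shift_samples)
  if (normalize) cfg <- normalize_configuration(cfg)
  cfg
}
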