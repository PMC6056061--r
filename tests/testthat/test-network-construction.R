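# Block extraction, correlation, sign split, configuration assembly and
# normalization.

test_that("extract_blocks applies the window shift and bounds-checks", {
  series <- list(values = matrix(seq_len(5 * 60), nrow = 5),
                 annotations = data.frame(subject = 1, task = "t",
                                          condition = "low", block = 1,
                                          onset_sample = 10, n_samples = 20))
  seg <- extract_blocks(series, shift_samples = 4)[[1]]
  expect_equal(ncol(seg$data), 20)
  # onset 10 + shift 4 -> samples 14..33 (half-open [14, 34))
  expect_equal(seg$data[1, 1], series$values[1, 14])
  expect_equal(seg$data[1, 20], series$values[1, 33])

  seg0 <- extract_blocks(series, shift_samples = 0)[[1]]
  expect_equal(seg0$data[1, 1], series$values[1, 10])

  series$annotations$onset_sample <- 45
  expect_error(extract_blocks(series, shift_samples = 4), "exceeds")
  expect_error(extract_blocks(series, shift_samples = -1), ">= 0")
})

test_that("block_correlation matches closed-form Pearson", {
  x <- c(1, 2, 3, 4)
  expect_equal(block_correlation(rbind(x, x))[1, 2], 1)
  expect_equal(block_correlation(rbind(x, -x))[1, 2], -1)
  # hand-computed: cov = 4, sd_x = sd_y = sqrt(5) (x10/3 scale cancels)
  expect_equal(block_correlation(rbind(x, c(1, 3, 2, 4)))[1, 2], 0.8)

  expect_error(block_correlation(matrix(1:4, 2, 2)), "3 samples")
  # constant region -> zero edges with warning
  X <- rbind(x, rep(1, 4), c(2, 1, 4, 3))
  expect_warning(C <- block_correlation(X), "constant")
  expect_equal(C[1, 2], 0)
  expect_equal(C[2, 3], 0)
  expect_equal(unname(diag(C)), rep(1, 3))
})

test_that("sign_split partitions and reconstructs", {
  C <- matrix(c(1, 0.5, -0.3, 0.5, 1, 0, -0.3, 0, 1), 3, 3)
  sp <- sign_split(C)
  expect_equal(sp$pos[1, 2], 0.5)
  expect_equal(sp$neg[1, 3], 0.3)
  expect_equal(sp$pos[1, 3], 0)
  expect_true(all(sp$pos >= 0) && all(sp$neg >= 0))
  # partition completeness off-diagonal
  D <- sp$pos - sp$neg
  diag(C) <- 0
  expect_equal(D, C)
  # all-positive input -> empty negative channel
  expect_true(all(sign_split(abs(C))$neg == 0))
})

test_that("configuration assembly has spec'd shape and ordering", {
  co <- tiny_cohort()
  cfg <- assemble_configuration(co$series, co$design)
  n <- co$design$n_regions
  expect_equal(nrow(cfg$mat), n * (n - 1) / 2)
  expect_equal(ncol(cfg$mat), 3 * 36 * 2)  # subjects x cells x channels
  expect_true(all(cfg$mat >= 0))
  # lexicographic column order
  expect_equal(order_observations <- netsubgraph:::order_observations(cfg$obs_meta),
               seq_len(ncol(cfg$mat)))
  # 1 subject, 1 task, 1 condition, 1 block -> T = 2 (both sign channels)
  d1 <- generate_design(n_subjects = 1, tasks = "t", conditions = "c",
                        blocks_per_condition = 1, samples_per_block = 20,
                        n_regions = 10, n_systems = 2, seed = 2)
  t1 <- generate_truth(d1, 1)
  cfg1 <- assemble_configuration(generate_bold(d1, t1), d1)
  expect_equal(ncol(cfg1$mat), 2)

  # missing block -> informative error
  broken <- co$series
  broken[[1]]$annotations <- broken[[1]]$annotations[-1, ]
  expect_error(assemble_configuration(broken, co$design), "missing design cell")
})

test_that("vectorize/reconstitute round-trips through the edge order", {
  set.seed(1)
  for (n in c(4, 7, 12)) {
    M <- matrix(rnorm(n * n), n, n)
    M <- M + t(M); diag(M) <- 0
    v <- vectorize_edges(M)
    expect_equal(length(v), n * (n - 1) / 2)
    expect_equal(edges_to_matrix(v), M)
    expect_equal(vectorize_edges(edges_to_matrix(v)), v)
  }
  # edge order is row-major upper triangle
  ei <- edge_index(4)
  expect_equal(ei$i, c(1, 1, 1, 2, 2, 3))
  expect_equal(ei$j, c(2, 3, 4, 3, 4, 4))
})

test_that("normalization steps behave as specified", {
  co <- tiny_cohort()
  cfg <- assemble_configuration(co$series, co$design)
  ncfg <- normalize_configuration(cfg)
  expect_true(ncfg$normalized)
  expect_true(all(ncfg$mat >= 0))
  # step 1 example: weights (1, 1, 2) -> (0.25, 0.25, 0.5); step 1 preserves
  # within-observation ordering (checked on a real column pair)
  col1_raw <- cfg$mat[, 1] / sum(cfg$mat[, 1])
  o <- order(cfg$mat[, 1])
  expect_true(all(diff(col1_raw[o]) >= 0))
  # step 2: per subject, each edge's observation vector has unit L2 norm
  # (or is all zero)
  for (s in 1:2) {
    cols <- which(ncfg$obs_meta$subject == s)
    nrms <- sqrt(rowSums(ncfg$mat[, cols]^2))
    expect_true(all(abs(nrms - 1) < 1e-10 | nrms == 0))
  }
  # step 2 is idempotent given step-1-stable input: renormalizing the
  # edge vectors again changes nothing
  m2 <- ncfg$mat
  for (s in unique(ncfg$obs_meta$subject)) {
    cols <- which(ncfg$obs_meta$subject == s)
    nrm <- sqrt(rowSums(m2[, cols, drop = FALSE]^2))
    nrm[nrm == 0] <- 1
    m2[, cols] <- m2[, cols] / nrm
  }
  expect_equal(m2, ncfg$mat)

  bad <- cfg
  bad$mat[, 3] <- 0
  expect_error(normalize_configuration(bad), "all-zero")
})

test_that("summarize_edge_strength computes paired tests and ANOVA", {
  co <- tiny_cohort()
  cfg <- assemble_configuration(co$series, co$design)
  for (g in c("task", "condition", "fixation_vs_task", "sign_channel")) {
    res <- summarize_edge_strength(cfg, g)
    expect_equal(nrow(res$means), 3)
    expect_true(is.finite(res$test$p.value))
  }
  res <- summarize_edge_strength(cfg, "subject")
  expect_match(res$test$method, "ANOVA")

  # hand-sized paired t: textbook formula
  x <- c(0.5, 0.7, 0.6); y <- c(0.4, 0.5, 0.65)
  d <- x - y
  tt <- netsubgraph:::paired_t(x, y)
  expect_equal(tt$statistic, mean(d) / (sd(d) / sqrt(3)))
  expect_equal(tt$p.value, 2 * pt(-abs(tt$statistic), 2))
  # identical groups -> t = 0, p = 1
  tt0 <- netsubgraph:::paired_t(x, x)
  expect_equal(tt0$statistic, 0)
  expect_equal(tt0$p.value, 1)
  # constant shift -> mean difference = shift
  tt_c <- netsubgraph:::paired_t(x + 0.2, x)
  expect_equal(tt_c$p.value, 0)
})
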