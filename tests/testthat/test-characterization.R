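# Expression summaries, core-periphery analytics, permutation tests,
# hierarchy correlations, contrasts.

make_summary <- function(H, meta) relative_expression(H, meta)

test_that("relative expression pairs channels and ranks subgraphs", {
  meta <- expand.grid(sign_channel = c("pos", "neg"), block = 1:2,
                      condition = c("low", "high"), task = "t", subject = 1:2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  Tn <- nrow(meta)
  H <- matrix(0, 2, Tn)
  H[1, meta$sign_channel == "pos"] <- 0.7
  H[1, meta$sign_channel == "neg"] <- 0.2
  H[2, ] <- 0.4  # equal channels
  summ <- relative_expression(H, meta)
  expect_equal(unique(summ$table$relative[summ$table$subgraph == 1]), 0.5)
  expect_equal(unique(summ$table$relative[summ$table$subgraph == 2]), 0)
  # ranking: subgraph 1 first (label A), positive class
  expect_equal(summ$ranking$subgraph, c(1, 2))
  expect_equal(summ$ranking$label, c("A", "B"))
  expect_equal(summ$ranking$class[1], "positive")
  # missing partner column errors
  expect_error(relative_expression(H[, -1, drop = FALSE], meta[-1, ]),
               "partner")
})

test_that("core-periphery index hits the three closed-form constructions", {
  part <- synthetic_partition(12, 3)
  a <- part$assignment
  within <- outer(a, a, "==") * 1; diag(within) <- 0
  between <- 1 - outer(a, a, "==") * 1; diag(between) <- 0
  expect_equal(core_periphery_index(within, part)$index, 1)
  expect_equal(core_periphery_index(between, part)$index, -1)
  # uniform complete graph, two systems of 2 in N = 4: the printed 1/|s|
  # normalization makes core_s = periphery_s exactly here -> index 0
  part4 <- synthetic_partition(4, 2)
  uniform4 <- matrix(1, 4, 4); diag(uniform4) <- 0
  expect_equal(core_periphery_index(uniform4, part4)$index, 0)
  # bounded on random subgraphs
  set.seed(12)
  for (i in 1:50) {
    W <- edges_to_matrix(runif(66), 12)
    idx <- core_periphery_index(W, part)$index
    expect_gte(idx, -1); expect_lte(idx, 1)
  }
  # degenerate inputs
  expect_error(core_periphery_index(within, synthetic_partition(12, 1)),
               "2 systems")
  bad <- within; diag(bad) <- 1
  expect_error(core_periphery_index(bad, part), "diagonal")
})

test_that("core/periphery permutation test flags a planted system", {
  part <- synthetic_partition(20, 4)
  W <- matrix(0.01, 20, 20); diag(W) <- 0
  in1 <- part$assignment == "S1"
  W[in1, in1] <- 1; diag(W) <- 0
  res <- system_core_periphery_test(W, part, n_perm = 1000, seed = 4)
  expect_lt(res$p_core_adj[res$system == "S1"], 0.05)
  # constant-weight subgraph: permutation-invariant, nothing significant,
  # p = 1 for all
  Wc <- matrix(0.5, 20, 20); diag(Wc) <- 0
  resc <- system_core_periphery_test(Wc, part, n_perm = 500, seed = 4)
  expect_true(all(resc$p_core == 1) && all(resc$p_periphery == 1))
  # plus-one lower bound
  expect_true(all(res$p_core >= 1 / 1001))
  expect_error(system_core_periphery_test(W, part, n_perm = 50), "n_perm")
})

test_that("system interaction test detects planted within-system weight", {
  part <- synthetic_partition(20, 4)
  W <- matrix(0.01, 20, 20); diag(W) <- 0
  in2 <- part$assignment == "S2"
  W[in2, in2] <- 1; diag(W) <- 0
  res <- system_interaction_test(W, part, n_perm = 1000, seed = 6)
  expect_lt(res$p_within_adj[res$system == "S2"], 0.05)
  # uniform subgraph: nothing significant
  Wc <- matrix(0.3, 20, 20); diag(Wc) <- 0
  resc <- system_interaction_test(Wc, part, n_perm = 500, seed = 6)
  expect_true(all(resc$p_within == 1) && all(resc$p_between == 1))
})

test_that("hierarchy correlation reproduces hand-ranked Spearman values", {
  meta <- expand.grid(sign_channel = c("pos", "neg"), block = 1:2,
                      condition = c("low", "high"),
                      task = c("t1", "t2"), subject = 1:3,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  Tn <- nrow(meta)
  set.seed(2)
  H <- matrix(runif(3 * Tn), 3, Tn)
  summ <- relative_expression(H, meta)
  same <- expression_hierarchy_correlation(summ, list(task = "t1"),
                                           list(task = "t1"))
  expect_equal(same$rho, 1)
  # hand case: ranks (1,2,3) vs (2,1,3) -> rho = 0.5
  expect_equal(cor(c(1, 2, 3), c(2, 1, 3), method = "spearman"), 0.5)
  # exactly reversed ranks -> rho = -1: subgraph k expressed at k * 0.2 in
  # t1 and (4 - k) * 0.2 in t2 (positive channel only)
  H3 <- matrix(0, 3, Tn)
  for (k in 1:3) {
    H3[k, meta$sign_channel == "pos" & meta$task == "t1"] <- k * 0.2
    H3[k, meta$sign_channel == "pos" & meta$task == "t2"] <- (4 - k) * 0.2
  }
  s2 <- relative_expression(H3, meta)
  rev <- expression_hierarchy_correlation(s2, list(task = "t1"),
                                          list(task = "t2"))
  expect_equal(rev$rho, -1)
})

test_that("contrast_expression applies BH over subgraphs", {
  # BH by hand: p = (.01, .02, .03, .5), q = .05 -> first three rejected
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH") < 0.05,
               c(TRUE, TRUE, TRUE, FALSE))

  meta <- expand.grid(sign_channel = c("pos", "neg"), block = 1:3,
                      condition = c("low", "high"), task = "t", subject = 1:6,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  Tn <- nrow(meta)
  set.seed(13)
  H <- matrix(runif(4 * Tn, 0.2, 0.4), 4, Tn)
  # subgraph 2: strong positive shift under high demand for every subject
  H[2, meta$condition == "high" & meta$sign_channel == "pos"] <- 2
  summ <- relative_expression(H, meta)
  res <- contrast_expression(summ, list(condition = "high"),
                             list(condition = "low"))
  expect_true(res$significant[res$subgraph == 2])
  expect_true(all(res$p_adj >= res$p))
  # identical groups -> t = 0, nothing significant
  res0 <- contrast_expression(summ, list(condition = "low"),
                              list(condition = "low"))
  expect_true(all(res0$statistic == 0) && !any(res0$significant))
  # BH monotone in raw p
  o <- order(res$p)
  expect_true(all(diff(res$p_adj[o]) >= -1e-12))
})

test_that("edge_contrast Fisher-transforms and FDR-corrects per channel", {
  expect_equal(atanh(0), 0)
  expect_equal(atanh(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(atanh(-0.5), -atanh(0.5))  # odd
  expect_true(all(diff(atanh(seq(-0.9, 0.9, 0.1))) > 0))  # increasing

  co <- tiny_cohort()
  cfg <- assemble_configuration(co$series, co$design)
  res <- edge_contrast(cfg, list(task = "stroop"), list(task = "navon"))
  expect_equal(nrow(res), 2 * nrow(cfg$mat))
  expect_true(all(res$p_adj >= res$p - 1e-12))
  # identical groups -> no significant edges
  res0 <- edge_contrast(cfg, list(task = "stroop"), list(task = "stroop"))
  expect_true(all(res0$statistic == 0) && !any(res0$significant))
  # clipping warning on saturated magnitudes
  cfg2 <- cfg
  cfg2$mat[1, ] <- 1
  expect_warning(edge_contrast(cfg2, list(task = "stroop"),
                               list(task = "navon")), "clipped")
})
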