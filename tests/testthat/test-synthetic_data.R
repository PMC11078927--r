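test_that("reference GRN simulation is deterministic and plants a reciprocal MR clique", {
  sc <- synthetic_scenario(seed = 7, n_tfs = 10, n_targets = 50,
                           n_planted_mrs = 2, targets_per_tf = 4)
  a <- simulate_reference_grn(sc)
  b <- simulate_reference_grn(sc)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$truth$planted_mrs, b$truth$planted_mrs)

  mrs <- a$truth$planted_mrs
  ed <- a$network$edges
  expect_true(any(ed$regulator == mrs[1] & ed$target == mrs[2]))
  expect_true(any(ed$regulator == mrs[2] & ed$target == mrs[1]))
  expect_true(all(mrs %in% a$network$nodes$gene[a$network$nodes$is_tf]))
})

test_that("planted MRs are out-degree hubs on average", {
  set.seed(100)
  diffs <- vapply(1:20, function(s) {
    sc <- synthetic_scenario(seed = s)
    sim <- simulate_reference_grn(sc)
    ed <- sim$network$edges
    outdeg <- table(factor(ed$regulator,
                           levels = sim$network$nodes$gene[sim$network$nodes$is_tf]))
    mrs <- sim$truth$planted_mrs
    mean(outdeg[mrs]) - mean(outdeg[setdiff(names(outdeg), mrs)])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("scenario validation rejects impossible parameterizations", {
  expect_error(synthetic_scenario(n_planted_mrs = 40, n_tfs = 30),
               "n_planted_mrs")
  expect_error(synthetic_scenario(targets_per_tf = 400, n_targets = 300),
               "targets_per_tf")
  expect_error(synthetic_scenario(dispersion = 0), "dispersion")
})

test_that("simulated counts are integer, deterministic, and recover planted means", {
  sc <- synthetic_scenario(seed = 3)
  sim <- simulate_reference_grn(sc)
  cm <- simulate_counts(sc, sim$truth)
  expect_true(all(cm$counts >= 0))
  expect_true(all(cm$counts == round(cm$counts)))
  expect_equal(ncol(cm$counts), 2 * sc$n_replicates)
  expect_identical(cm$counts, simulate_counts(sc, sim$truth)$counts)

  # planted MR fold change recovered within 25% when pooled over 10 seeds
  ratios <- unlist(lapply(1:10, function(s) {
    sc <- synthetic_scenario(seed = s)
    sim <- simulate_reference_grn(sc)
    cm <- simulate_counts(sc, sim$truth)
    ctl <- cm$sample_meta$condition == "control"
    rowMeans(cm$counts[sim$truth$planted_mrs, !ctl, drop = FALSE]) /
      rowMeans(cm$counts[sim$truth$planted_mrs, ctl, drop = FALSE])
  }))
  expect_lt(abs(mean(ratios) - 2^sc$mr_log2fc) / 2^sc$mr_log2fc, 0.25)
})

test_that("null effects make the two conditions exchangeable", {
  sc <- synthetic_scenario(seed = 11, mr_log2fc = 0, cascade_log2fc = 0,
                           frac_low_expressed_tfs = 0)
  sim <- simulate_reference_grn(sc)
  cm <- simulate_counts(sc, sim$truth)
  ctl <- cm$sample_meta$condition == "control"
  lfc <- log2(rowMeans(cm$counts[, !ctl]) / rowMeans(cm$counts[, ctl]))
  expect_lt(abs(mean(lfc)), 0.1)
})

test_that("low-expressed TFs fall below the 10-count cutoff in the case condition", {
  sc <- synthetic_scenario(seed = 2)
  sim <- simulate_reference_grn(sc)
  cm <- simulate_counts(sc, sim$truth)
  low <- sim$truth$low_expressed_tfs
  expect_equal(length(low), round(0.2 * sc$n_tfs))
  st <- expression_status(cm, "case")
  expect_true(all(!st$expressed[st$gene %in% low]))
  st_ctl <- expression_status(cm, "control")
  expect_true(all(st_ctl$expressed[st_ctl$gene %in% low]))
})

test_that("noiseless qPCR simulation matches the ddCt closed form", {
  sc <- synthetic_scenario(seed = 5, mr_log2fc = 1)
  sim <- simulate_reference_grn(sc)
  qp <- simulate_qpcr(sim$truth, n_control = 3, n_case = 3, seed = 9,
                      noise_sd = 0)
  expect_identical(qp, simulate_qpcr(sim$truth, 3, 3, seed = 9, noise_sd = 0))
  for (g in sim$truth$planted_mrs) {
    rel <- ddct_relative_expression(qp, "Gapdh", g)
    expect_equal(rel$ddct[rel$group == "case"], rep(-1, 3))
    expect_equal(rel$rq[rel$group == "case"], rep(2, 3))
    expect_equal(rel$rq[rel$group == "control"], rep(1, 3))
  }
})
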