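test_that("median-of-ratios size factors match hand-evaluated cases", {
  m <- matrix(c(2, 8, 4, 16), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- estimate_size_factors(make_cm(m))
  expect_equal(unname(sf), c(0.7071, 1.4142), tolerance = 1e-4)

  # identical columns give unit size factors
  m2 <- matrix(rep(c(5, 9, 40), 3), 3, 3,
               dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  expect_equal(unname(estimate_size_factors(make_cm(m2, c("control", "case", "control")))),
               rep(1, 3))

  # permutation equivariance
  set.seed(1)
  m3 <- matrix(rpois(40, 100), 10, 4,
               dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
  sf3 <- estimate_size_factors(make_cm(m3))
  perm <- c(3, 1, 4, 2)
  sf_perm <- estimate_size_factors(make_cm(m3[, perm]))
  expect_equal(unname(sf_perm), unname(sf3[perm]))

  # no all-positive reference gene -> informative error
  m4 <- matrix(c(0, 1, 1, 0), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(estimate_size_factors(make_cm(m4)), "pseudo-reference")
})

test_that("dispersion estimation floors Poisson-like genes and recovers alpha", {
  # constant gene and Poisson-like gene hit the floor
  m <- matrix(c(10, 10, 10, 10,
                9, 11, 10, 10), 2, 4, byrow = TRUE,
              dimnames = list(c("const", "poislike"), sprintf("s%d", 1:4)))
  cm <- make_cm(m, c("control", "control", "case", "case"))
  sf <- setNames(rep(1, 4), colnames(m))
  disp <- estimate_dispersions(cm, sf, setNames(cm$sample_meta$condition,
                                                colnames(m)))
  expect_equal(unname(disp), rep(1e-8, 2))

  # Monte-Carlo recovery at alpha = 0.1, n = 50 per group
  set.seed(77)
  n <- 50
  counts <- matrix(rnbinom(500 * 2 * n, mu = 200, size = 10), 500, 2 * n,
                   dimnames = list(sprintf("g%03d", 1:500),
                                   sprintf("s%03d", seq_len(2 * n))))
  cm <- make_cm(counts, rep(c("control", "case"), each = n))
  sf <- estimate_size_factors(cm)
  disp <- estimate_dispersions(cm, sf, setNames(cm$sample_meta$condition,
                                                colnames(counts)))
  expect_gt(median(disp), 0.05)
  expect_lt(median(disp), 0.2)

  expect_error(
    estimate_dispersions(cm, sf,
                         setNames(c("control", rep("case", 2 * n - 1)),
                                  colnames(counts))),
    "fewer than 2 samples")
})

test_that("Wald test estimates the log2 fold change consistently", {
  set.seed(5)
  n <- 50
  mu <- rep(c(100, 400), each = n)
  counts <- matrix(rnbinom(200 * 2 * n, mu = rep(mu, each = 200), size = 100),
                   200, 2 * n,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   sprintf("s%03d", seq_len(2 * n))))
  cm <- make_cm(counts, rep(c("control", "case"), each = n))
  sf <- setNames(rep(1, 2 * n), colnames(counts))
  groups <- setNames(cm$sample_meta$condition, colnames(counts))
  disp <- estimate_dispersions(cm, sf, groups)
  det <- nb_wald_test(cm, sf, disp, groups)
  expect_lt(abs(median(det$log2fc) - 2), 0.1)
  expect_true(all(det$p[det$log2fc > 1] < 0.01))
})

test_that("all-zero genes are untested and never propagate NaN", {
  m <- matrix(c(0, 0, 0, 0,
                5, 6, 50, 60), 2, 4, byrow = TRUE,
              dimnames = list(c("zero", "real"), sprintf("s%d", 1:4)))
  cm <- make_cm(m, c("control", "control", "case", "case"))
  sf <- setNames(rep(1, 4), colnames(m))
  groups <- setNames(cm$sample_meta$condition, colnames(m))
  det <- nb_wald_test(cm, sf, estimate_dispersions(cm, sf, groups), groups)
  expect_true(is.na(det$p[det$gene_id == "zero"]))
  expect_identical(det$status[det$gene_id == "zero"], "untested")
  expect_false(any(is.nan(unlist(det[det$gene_id == "real",
                                     c("log2fc", "p")]))))
  res <- classify_degs(transform(det, padj = bh_adjust(p)), de_thresholds())
  expect_identical(res$table$status[res$table$gene_id == "zero"], "untested")
})

test_that("BH adjustment matches hand evaluation and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(123)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # order-preserving under rank
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }

  # NA entries are excluded from m and stay NA
  p <- c(0.01, NA, 0.02, 0.03)
  expect_equal(bh_adjust(p), c(0.03, NA, 0.03, 0.03))
})

test_that("DEG classification honors alpha and fold-change thresholds", {
  det <- data.frame(gene_id = c("a", "b", "c", "d"),
                    base_mean = 10, log2fc = c(3, 1, -2.5, 0.1),
                    dispersion = 0.1,
                    p = c(0.001, 0.15, 0.001, 0.5),
                    padj = c(0.04, 0.2, 0.01, 0.8),
                    status = NA_character_, stringsAsFactors = FALSE)
  res <- classify_degs(det, de_thresholds(alpha = 0.05, fc_threshold = 0))
  expect_equal(res$table$status, c("up", "ns", "down", "ns"))
  expect_equal(res$summary$n_up, 1)
  expect_equal(res$summary$n_down, 1)

  res2 <- classify_degs(det, de_thresholds(alpha = 0.05, fc_threshold = 2))
  expect_equal(res2$table$status, c("up", "ns", "down", "ns"))
  res3 <- classify_degs(det, de_thresholds(alpha = 0.05, fc_threshold = 3))
  expect_equal(res3$table$status, c("ns", "ns", "ns", "ns"))
})

test_that("size factors absorb a constant rescaling of one sample", {
  sc <- synthetic_scenario(seed = 4)
  sim <- simulate_reference_grn(sc)
  cm <- simulate_counts(sc, sim$truth)
  de1 <- run_de(cm)
  scaled <- cm$counts
  scaled[, 3] <- scaled[, 3] * 2L
  de2 <- run_de(count_matrix(scaled, cm$sample_meta))
  ok <- !is.na(de1$table$log2fc)
  expect_lt(max(abs(de1$table$log2fc[ok] - de2$table$log2fc[ok])), 0.05)
})
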