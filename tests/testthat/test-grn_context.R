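test_that("reference union deduplicates, merges sources and flags conflicts", {
  trrust <- make_edge_df("A", "B", "activation", "trrust")
  dorothea <- make_edge_df("A", "B", "activation", "dorothea", "A")
  net <- build_reference_network(list(trrust, dorothea))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$sources, "dorothea;trrust")
  expect_equal(net$edges$mode, "activation")
  expect_equal(net$edges$confidence, "A")

  regnet <- make_edge_df("A", "B", "repression", "regnetwork")
  net2 <- build_reference_network(list(trrust, regnet))
  expect_equal(net2$edges$mode, "ambiguous")

  # unknown never overrides an informative mode
  net3 <- build_reference_network(list(trrust,
                                       make_edge_df("A", "B", "unknown", "x")))
  expect_equal(net3$edges$mode, "activation")

  expect_error(build_reference_network(list(trrust[0, ])), "empty")
})

test_that("union size is bounded by the concatenation, with equality iff disjoint", {
  set.seed(21)
  for (i in 1:20) {
    lists <- lapply(1:3, function(j) {
      n <- sample(1:15, 1)
      make_edge_df(sample(LETTERS[1:6], n, replace = TRUE),
                   sample(letters[1:6], n, replace = TRUE),
                   sources = paste0("db", j))
    })
    net <- build_reference_network(lists)
    concat <- do.call(rbind, lists)
    keys <- paste(concat$regulator, concat$target)
    expect_equal(nrow(net$edges), length(unique(keys)))
    expect_lte(nrow(net$edges), nrow(concat))
    if (!anyDuplicated(keys)) expect_equal(nrow(net$edges), nrow(concat))
  }
})

test_that("expression status uses the condition mean with an inclusive boundary", {
  m <- matrix(c(9, 9, 9, 9,
                10, 10, 10, 10,
                0, 40, 0, 0), 3, 4, byrow = TRUE,
              dimnames = list(c("below", "at", "spiky"), sprintf("s%d", 1:4)))
  cm <- make_cm(m, rep("case", 4))
  st <- expression_status(cm, "case", tau = 10)
  expect_false(st$expressed[st$gene == "below"])
  expect_true(st$expressed[st$gene == "at"])
  expect_true(st$expressed[st$gene == "spiky"])  # mean 10 inclusive
  st_min <- expression_status(cm, "case", tau = 10, aggregate = "min")
  expect_false(st_min$expressed[st_min$gene == "spiky"])
  expect_error(expression_status(cm, "control"), "no samples")
})

test_that("contextualization removes only outgoing edges of silent TFs", {
  net <- make_network(c("X", "B"), c("A", "X"))
  status <- data.frame(gene = c("B", "A"), mean_raw_count = 50,
                       expressed = TRUE)
  ctx <- contextualize(net, status)  # X not in status -> not expressed
  expect_equal(nrow(ctx$edges), 1)
  expect_equal(ctx$edges$regulator, "B")
  expect_equal(ctx$edges$target, "X")  # incoming edge to X kept
  expect_false("A" %in% ctx$nodes$gene)  # degree-0 node dropped

  # all TFs expressed -> identity
  status_all <- data.frame(gene = c("X", "B", "A"), mean_raw_count = 50,
                           expressed = TRUE)
  expect_equal(contextualize(net, status_all)$edges, net$edges)

  # no TF expressed -> empty edge set
  status_none <- data.frame(gene = c("X", "B", "A"), mean_raw_count = 0,
                            expressed = FALSE)
  expect_equal(nrow(contextualize(net, status_none)$edges), 0)
})

test_that("contextualization is idempotent, tau-monotone and oracle-equal", {
  set.seed(33)
  for (i in 1:25) {
    net <- random_network(max_n = 8, p = 0.3)
    genes <- net$nodes$gene
    counts <- matrix(rpois(length(genes) * 4, 12), length(genes), 4,
                     dimnames = list(genes, sprintf("s%d", 1:4)))
    cm <- make_cm(counts, rep("case", 4))
    st <- expression_status(cm, "case", tau = 12)
    ctx <- contextualize(net, st)
    expect_identical(contextualize(ctx, st)$edges, ctx$edges)
    expect_identical(ctx$edges,
                     oracle_contextualize_edges(net$edges,
                                                st$gene[st$expressed]))
    # raising tau never adds edges
    st_hi <- expression_status(cm, "case", tau = 15)
    ctx_hi <- contextualize(net, st_hi)
    expect_true(all(paste(ctx_hi$edges$regulator, ctx_hi$edges$target) %in%
                    paste(ctx$edges$regulator, ctx$edges$target)))
  }
})
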