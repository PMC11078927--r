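test_that("upstream neighborhood keeps first and second regulators only", {
  net <- make_network(c("A", "B", "C"), c("B", "g", "A"))
  sub <- upstream_neighborhood(net, "g")
  expect_setequal(sub$nodes$gene, c("g", "B", "A"))  # C is 3 steps away
  expect_setequal(paste(sub$edges$regulator, sub$edges$target),
                  c("A B", "B g"))

  # DEG with no regulators is a single isolated node
  net2 <- make_network("A", "B", nodes = c("A", "B", "lonely"))
  sub2 <- upstream_neighborhood(net2, "lonely")
  expect_equal(sub2$nodes$gene, "lonely")
  expect_equal(nrow(sub2$edges), 0)

  # saturation: all nodes as DEGs gives the whole network back
  sub3 <- upstream_neighborhood(net, c("A", "B", "C", "g"))
  expect_setequal(sub3$nodes$gene, net$nodes$gene)
  expect_equal(nrow(sub3$edges), nrow(net$edges))

  expect_warning(upstream_neighborhood(net, c("g", "absent")), "absent from")
  expect_error(upstream_neighborhood(net, "nope"), "symbol space")
})

test_that("core pruning follows the hand-traced example", {
  net <- make_network(c("M1", "M1", "M2", "M2", "M1", "M2"),
                      c("g1", "g2", "g2", "g3", "M2", "M1"))
  res <- iterative_core_pruning(net)
  expect_setequal(res$survivors$nodes$gene, c("M1", "M2"))
  # min out-degree first, ties by min in-degree then lexicographic id:
  # g1 (in 1), then g3 (in 1) before g2 (in 2)
  expect_equal(res$trace$node, c("g1", "g3", "g2"))
  expect_equal(res$trace$out_degree_at_removal, c(0L, 0L, 0L))
  expect_equal(res$blocked$blocked_node, "M1")
  expect_equal(res$blocked$reason, "disconnection")
})

test_that("core pruning boundary rules: tiny and degenerate inputs", {
  # two nodes: removing either leaves < 2 nodes, blocked immediately
  net <- make_network("A", "B")
  res <- iterative_core_pruning(net)
  expect_setequal(res$survivors$nodes$gene, c("A", "B"))
  expect_equal(nrow(res$trace), 0)

  # single node survives with an empty trace
  one <- regulatory_network(make_edge_df(character(), character()),
                            data.frame(gene = "solo", is_tf = FALSE))
  res1 <- iterative_core_pruning(one)
  expect_equal(res1$survivors$nodes$gene, "solo")
  expect_equal(nrow(res1$trace), 0)

  # empty network
  empty <- regulatory_network(make_edge_df(character(), character()))
  res0 <- iterative_core_pruning(empty)
  expect_equal(nrow(res0$survivors$nodes), 0)
  expect_equal(nrow(res0$trace), 0)

  # self-loops count toward degrees but never carry connectivity
  loopy <- make_network(c("A", "A", "B"), c("A", "B", "A"))
  resl <- iterative_core_pruning(loopy)
  expect_setequal(resl$survivors$nodes$gene, c("A", "B"))
})

test_that("pruning is deterministic, trace-replayable and oracle-minimal", {
  set.seed(55)
  for (i in 1:40) {
    net <- random_network(max_n = 10, p = 0.25)
    res <- iterative_core_pruning(net)
    res2 <- iterative_core_pruning(net)
    expect_identical(res$trace, res2$trace)
    expect_identical(res$survivors$nodes$gene, res2$survivors$nodes$gene)
    expect_true(replay_trace(net, res$trace, res$survivors))
    oracle <- oracle_core_pruning(net)
    expect_identical(sort(res$survivors$nodes$gene), oracle$survivors)
    expect_identical(res$trace$node, oracle$trace$node)
    expect_identical(res$trace$out_degree_at_removal,
                     oracle$trace$out_degree_at_removal)
    # each weak component of the survivors is weakly connected
    if (nrow(res$survivors$nodes) > 0) {
      g <- igraph::graph_from_data_frame(
        res$survivors$edges[, c("regulator", "target")], directed = TRUE,
        vertices = data.frame(name = res$survivors$nodes$gene))
      input_comps <- igraph::components(
        igraph::graph_from_data_frame(
          net$edges[, c("regulator", "target")], directed = TRUE,
          vertices = data.frame(name = net$nodes$gene)), mode = "weak")$no
      expect_lte(igraph::components(g, mode = "weak")$no, input_comps)
    }
  }
})

test_that("skip-blockers variant prunes at least as deep", {
  set.seed(66)
  for (i in 1:10) {
    net <- random_network(max_n = 8, p = 0.3)
    stop_first <- iterative_core_pruning(net)
    skipping <- iterative_core_pruning(net, skip_blockers = TRUE)
    expect_lte(nrow(skipping$survivors$nodes), nrow(stop_first$survivors$nodes))
    expect_true(all(skipping$survivors$nodes$gene %in% net$nodes$gene))
  }
})

test_that("candidate annotation reports degrees, DE status, reciprocity and physical support", {
  net <- make_network(c("M1", "M2", "M1", "M2"), c("M2", "M1", "g1", "g1"))
  det <- data.frame(gene_id = c("M1", "g1"), base_mean = 10,
                    log2fc = c(2, 3), dispersion = 0.1, p = 0.001,
                    padj = 0.01, status = c("up", "up"),
                    stringsAsFactors = FALSE)
  phys <- data.frame(protein_a = "M1", protein_b = "M2", combined_score = 900)
  cand <- annotate_candidates(net, det, phys)
  expect_setequal(cand$gene, c("M1", "M2"))  # g1 is not a TF
  expect_true(all(cand$reciprocal))
  expect_true(all(cand$physical_support))
  expect_equal(cand$out_degree[cand$gene == "M1"], 2L)
  expect_equal(cand$in_degree[cand$gene == "M1"], 1L)
  expect_equal(cand$direction, c("up", "none"))
  expect_equal(cand$is_de, c(TRUE, FALSE))  # M2 absent from det -> not DE

  # without a physical table support is unknown
  cand2 <- annotate_candidates(net, det)
  expect_true(all(is.na(cand2$physical_support)))

  # self-loop gives neither reciprocity nor physical support by itself
  loop <- make_network("T1", "T1")
  cl <- annotate_candidates(loop, NULL,
                            data.frame(protein_a = "T1", protein_b = "T1",
                                       combined_score = 999))
  expect_false(cl$reciprocal)
  expect_false(cl$physical_support)
})

test_that("master regulator selection splits on differential expression", {
  cand <- data.frame(
    gene = c("Lef1", "Jup", "Dnmt1", "Mybl2", "Foxo3", "Trp53", "Foxo1", "Ar"),
    out_degree = 3L, in_degree = 2L,
    is_de = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    direction = c("up", "up", "up", "up", "down", "none", "none", "none"),
    reciprocal = TRUE, physical_support = NA, stringsAsFactors = FALSE)
  sel <- select_master_regulators(cand)
  expect_equal(nrow(sel$all_mrs), 8)
  expect_setequal(sel$de_mrs$gene, c("Lef1", "Jup", "Dnmt1", "Mybl2", "Foxo3"))
  expect_equal(sel$de_mrs$direction[sel$de_mrs$gene == "Foxo3"], "down")

  none <- cand; none$is_de <- FALSE; none$direction <- "none"
  expect_equal(nrow(select_master_regulators(none)$de_mrs), 0)
  all_de <- cand; all_de$is_de <- TRUE
  expect_equal(nrow(select_master_regulators(all_de)$de_mrs), 8)
})
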