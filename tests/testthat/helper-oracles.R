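# Independent oracle implementations and fixture builders used across the
# suite. Oracles are deliberately naive and share no code with the package:
# the pruning oracle is igraph-based, the BH oracle is the textbook step-up
# formula, the contextualization oracle is a one-line edge filter.

make_edge_df <- function(regulator, target, mode = "activation",
                         sources = "test", confidence = NA_character_) {
  data.frame(regulator = regulator, target = target,
             mode = rep_len(mode, length(regulator)),
             sources = rep_len(sources, length(regulator)),
             confidence = rep_len(confidence, length(regulator)),
             stringsAsFactors = FALSE)
}

make_network <- function(regulator, target, nodes = NULL, ...) {
  ed <- make_edge_df(regulator, target, ...)
  if (is.null(nodes)) return(regulatory_network(ed))
  regulatory_network(ed, data.frame(gene = nodes,
                                    is_tf = nodes %in% regulator,
                                    stringsAsFactors = FALSE))
}

make_cm <- function(counts, condition = NULL, tissue = "colon") {
  if (is.null(condition)) {
    condition <- rep(c("control", "case"), length.out = ncol(counts))
  }
  meta <- data.frame(sample_id = colnames(counts),
                     tissue = rep_len(tissue, ncol(counts)),
                     condition = condition, batch = "b1",
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

# Random simple directed graph (self-loops allowed) on up to `max_n` nodes,
# returned as a regulatory_network that keeps isolated nodes.
random_network <- function(max_n = 10, p = 0.25) {
  n <- sample(2:max_n, 1)
  nodes <- sprintf("n%02d", seq_len(n))
  grid <- expand.grid(regulator = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  grid <- grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
  regulatory_network(make_edge_df(grid$regulator, grid$target),
                     data.frame(gene = nodes,
                                is_tf = nodes %in% grid$regulator,
                                stringsAsFactors = FALSE))
}

# Naive step-by-step pruning oracle built on igraph: same rules (min
# out-degree, ties by min in-degree then lexicographic id; stop when a
# removal would leave < 2 nodes or a weakly disconnected remainder; weak
# components processed independently, ordered by smallest member).
oracle_core_pruning <- function(net) {
  g0 <- igraph::graph_from_data_frame(
    net$edges[, c("regulator", "target"), drop = FALSE], directed = TRUE,
    vertices = data.frame(name = net$nodes$gene, stringsAsFactors = FALSE))
  comp <- igraph::components(g0, mode = "weak")
  groups <- split(names(comp$membership), comp$membership)
  groups <- groups[order(vapply(groups, min, character(1)))]
  survivors <- character()
  trace <- list()
  for (members in groups) {
    g <- igraph::induced_subgraph(g0, members)
    repeat {
      if (igraph::vcount(g) < 2) break
      nm <- igraph::V(g)$name
      outd <- igraph::degree(g, mode = "out", loops = TRUE)
      ind <- igraph::degree(g, mode = "in", loops = TRUE)
      v <- nm[order(unname(outd), unname(ind), nm)][1]
      g2 <- igraph::delete_vertices(g, v)
      if (igraph::vcount(g2) < 2 ||
          !igraph::is_connected(g2, mode = "weak")) break
      trace[[length(trace) + 1L]] <-
        data.frame(node = v, out_degree_at_removal = as.integer(unname(outd[v])),
                   stringsAsFactors = FALSE)
      g <- g2
    }
    survivors <- c(survivors, igraph::V(g)$name)
  }
  trace <- if (length(trace) > 0) do.call(rbind, trace) else
    data.frame(node = character(), out_degree_at_removal = integer(),
               stringsAsFactors = FALSE)
  list(survivors = sort(survivors), trace = trace)
}

# Textbook BH step-up: adjusted p = min over j >= rank of p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric())
  o <- order(p)
  stepped <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  pmin(adj, 1)[order(o)]
}

# One-line contextualization oracle: keep an edge iff its regulator is in
# the expressed set.
oracle_contextualize_edges <- function(edges, expressed) {
  out <- edges[edges$regulator %in% expressed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Replay a pruning trace against the input network: remove the recorded
# nodes in order and check the remainder matches the survivors.
replay_trace <- function(net, trace, survivors) {
  remaining <- setdiff(net$nodes$gene, trace$node)
  setequal(remaining, survivors$nodes$gene)
}
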