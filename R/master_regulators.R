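# Master regulator inference: induce the first/second upstream neighborhood
# of the differentially expressed genes in a contextualized network, then
# iteratively delete the node with the lowest out-degree until any further
# removal would disconnect the network (weakly) or leave fewer than two
# nodes. Surviving transcription factors are the master regulator
# candidates; those that are themselves differentially expressed are the
# reported master regulators.
#
# Conventions the source material leaves open, fixed here:
#  - "unconnected" means weak disconnection of the directed graph;
#  - ties at the minimal out-degree break by minimal in-degree, then
#    lexicographic node id, making the procedure fully deterministic;
#  - one node is removed per iteration, and the first blocking removal stops
#    the whole procedure (a `skip_blockers` variant that instead tries the
#    next-lowest node is available but non-default);
#  - self-loops count once toward out-degree and once toward in-degree and
#    never affect connectivity;
#  - every node is eligible for removal, but only reference TFs become
#    candidates (pure targets have out-degree 0 and fall first anyway).

#' Induce the first and second upstream neighborhood of a DEG set
#'
#' Retains the DEGs present in the network together with every node that
#' has a directed path of length 1 or 2 to some DEG (its first or second
#' upstream neighbors), and all edges of the network among the retained
#' nodes (induced subgraph). DEGs absent from the network are ignored with
#' a warning.
#'
#' @param net A [regulatory_network].
#' @param degs Character vector of differentially expressed gene symbols.
#' @return The induced [regulatory_network].
#' @export
upstream_neighborhood <- function(net, degs) {
  stopifnot(inherits(net, "regulatory_network"))
  degs <- unique(degs)
  present <- intersect(degs, net$nodes$gene)
  if (length(present) == 0) {
    stop("none of the differentially expressed genes occur in the network; ",
         "check that both use the same gene symbol space", call. = FALSE)
  }
  if (length(present) < length(degs)) {
    warning(sprintf("%d of %d DEGs are absent from the network and were ignored",
                    length(degs) - length(present), length(degs)),
            call. = FALSE)
  }
  first <- net$edges$regulator[net$edges$target %in% present]
  second <- net$edges$regulator[net$edges$target %in% first]
  keep <- unique(c(present, first, second))
  edges <- net$edges[net$edges$regulator %in% keep &
                     net$edges$target %in% keep, , drop = FALSE]
  nodes <- net$nodes[net$nodes$gene %in% keep, , drop = FALSE]
  regulatory_network(edges, nodes)
}

# Internal: weak connectivity by breadth-first search over the undirected
# skeleton; self-loops are ignored. `nodes` is a character vector, `el` a
# two-column character matrix of edges among `nodes`.
.weakly_connected <- function(nodes, el) {
  n <- length(nodes)
  if (n <= 1) return(TRUE)
  from <- match(el[, 1], nodes)
  to <- match(el[, 2], nodes)
  keep <- from != to
  adj <- vector("list", n)
  if (any(keep)) {
    from <- from[keep]; to <- to[keep]
    pairs <- split(c(to, from), c(from, to))
    adj[as.integer(names(pairs))] <- pairs
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    nb <- adj[[v]]
    nb <- nb[!seen[nb]]
    if (length(nb) > 0) {
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  all(seen)
}

# Internal: weak components as a list of character vectors, ordered by each
# component's lexicographically smallest member.
.weak_components <- function(nodes, el) {
  n <- length(nodes)
  comp <- integer(n)
  from <- match(el[, 1], nodes)
  to <- match(el[, 2], nodes)
  keep <- from != to
  adj <- vector("list", n)
  if (any(keep)) {
    from <- from[keep]; to <- to[keep]
    pairs <- split(c(to, from), c(from, to))
    adj[as.integer(names(pairs))] <- pairs
  }
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[v]]
      nb <- nb[comp[nb] == 0L]
      if (length(nb) > 0) {
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }
  comps <- split(nodes, comp)
  comps[order(vapply(comps, min, character(1)))]
}

# Internal: prune one weakly connected component. Returns surviving node
# names, a trace data frame and the terminal blocking event (or NULL).
.prune_component <- function(nodes, el, skip_blockers = FALSE) {
  present <- sort(nodes)
  trace <- list()
  blocked <- NULL
  repeat {
    if (length(present) < 2) break
    sub <- el[el[, 1] %in% present & el[, 2] %in% present, , drop = FALSE]
    out_deg <- table(factor(sub[, 1], levels = present))
    in_deg <- table(factor(sub[, 2], levels = present))
    ord <- order(as.integer(out_deg), as.integer(in_deg), present)
    committed <- FALSE
    for (i in ord) {
      v <- present[i]
      rem_nodes <- setdiff(present, v)
      rem_el <- sub[sub[, 1] != v & sub[, 2] != v, , drop = FALSE]
      if (length(rem_nodes) < 2 || !.weakly_connected(rem_nodes, rem_el)) {
        if (is.null(blocked)) {
          blocked <- data.frame(blocked_node = v, reason = "disconnection",
                                stringsAsFactors = FALSE)
        }
        if (!skip_blockers) break
      } else {
        trace[[length(trace) + 1L]] <-
          data.frame(node = v, out_degree_at_removal = as.integer(out_deg[i]),
                     stringsAsFactors = FALSE)
        present <- rem_nodes
        committed <- TRUE
        blocked <- if (skip_blockers) NULL else blocked
        break
      }
    }
    if (!committed) break
  }
  trace <- if (length(trace) > 0) do.call(rbind, trace) else
    data.frame(node = character(), out_degree_at_removal = integer(),
               stringsAsFactors = FALSE)
  list(survivors = present, trace = trace, blocked = blocked)
}

#' Iterative lowest-out-degree core pruning
#'
#' Repeatedly removes the node with the minimal current out-degree (ties:
#' minimal in-degree, then lexicographic id) together with its incident
#' edges; a removal that would leave fewer than two nodes or a weakly
#' disconnected remainder is undone and stops the procedure. A network that
#' is not weakly connected to begin with is pruned per weak component and
#' the results merged.
#'
#' @param net A [regulatory_network].
#' @param skip_blockers If `TRUE`, a blocking removal is skipped and the
#'   next-lowest node is tried instead, stopping only when every remaining
#'   node blocks; default `FALSE` (stop at the first block).
#' @return List with elements `survivors` (the surviving
#'   [regulatory_network]), `trace` (data frame `step`, `node`,
#'   `out_degree_at_removal`, `component`) and `blocked` (data frame
#'   `component`, `blocked_node`, `reason`, one row per component that hit a
#'   blocking removal).
#' @export
iterative_core_pruning <- function(net, skip_blockers = FALSE) {
  stopifnot(inherits(net, "regulatory_network"))
  nodes <- net$nodes$gene
  el <- cbind(net$edges$regulator, net$edges$target)
  empty_trace <- data.frame(step = integer(), node = character(),
                            out_degree_at_removal = integer(),
                            component = integer(), stringsAsFactors = FALSE)
  empty_blocked <- data.frame(component = integer(),
                              blocked_node = character(),
                              reason = character(), stringsAsFactors = FALSE)
  if (length(nodes) == 0) {
    return(list(survivors = regulatory_network(net$edges[0, ], net$nodes[0, ]),
                trace = empty_trace, blocked = empty_blocked))
  }
  comps <- .weak_components(nodes, el)
  traces <- list()
  blocked <- list()
  survivors <- character()
  for (ci in seq_along(comps)) {
    sub_el <- el[el[, 1] %in% comps[[ci]], , drop = FALSE]
    res <- .prune_component(comps[[ci]], sub_el, skip_blockers = skip_blockers)
    survivors <- c(survivors, res$survivors)
    if (nrow(res$trace) > 0) {
      res$trace$component <- ci
      traces[[length(traces) + 1L]] <- res$trace
    }
    if (!is.null(res$blocked)) {
      res$blocked$component <- ci
      blocked[[length(blocked) + 1L]] <- res$blocked
    }
  }
  trace <- if (length(traces) > 0) do.call(rbind, traces) else empty_trace
  if (nrow(trace) > 0) {
    trace$step <- seq_len(nrow(trace))
    trace <- trace[, c("step", "node", "out_degree_at_removal", "component"),
                   drop = FALSE]
  }
  blk <- if (length(blocked) > 0) {
    b <- do.call(rbind, blocked)
    b[, c("component", "blocked_node", "reason"), drop = FALSE]
  } else empty_blocked
  keep_edges <- net$edges$regulator %in% survivors &
    net$edges$target %in% survivors
  surv_net <- regulatory_network(
    net$edges[keep_edges, , drop = FALSE],
    net$nodes[net$nodes$gene %in% survivors, , drop = FALSE])
  list(survivors = surv_net, trace = trace, blocked = blk)
}

#' Annotate master regulator candidates
#'
#' One candidate per surviving node that is a transcription factor in the
#' reference network: degrees within the survivor subgraph (self-loops
#' count once each), differential-expression status and direction from the
#' DE table, reciprocity (at least one outgoing and one incoming edge with
#' *other* survivors), and physical support (some unordered survivor pair
#' containing the node occurs in the interaction table; `NA` when no table
#' is supplied).
#'
#' @param survivors Surviving [regulatory_network] from
#'   [iterative_core_pruning()].
#' @param det Differential-expression table with `status` filled (genes
#'   absent from it count as not differentially expressed).
#' @param physical Optional pair table from [read_physical_pairs()].
#' @return Data frame with columns `gene`, `out_degree`, `in_degree`,
#'   `is_de`, `direction`, `reciprocal`, `physical_support`.
#' @export
annotate_candidates <- function(survivors, det = NULL, physical = NULL) {
  stopifnot(inherits(survivors, "regulatory_network"))
  tfs <- sort(survivors$nodes$gene[survivors$nodes$is_tf])
  ed <- survivors$edges
  out_deg <- table(factor(ed$regulator, levels = tfs))
  in_deg <- table(factor(ed$target, levels = tfs))
  non_self_out <- table(factor(ed$regulator[ed$regulator != ed$target],
                               levels = tfs))
  non_self_in <- table(factor(ed$target[ed$regulator != ed$target],
                              levels = tfs))
  status <- rep("ns", length(tfs))
  if (!is.null(det)) {
    m <- match(tfs, det$gene_id)
    status[!is.na(m)] <- det$status[m[!is.na(m)]]
  }
  is_de <- status %in% c("up", "down")
  direction <- ifelse(is_de, status, "none")
  physical_support <- rep(NA, length(tfs))
  if (!is.null(physical)) {
    surv <- survivors$nodes$gene
    in_net <- physical$protein_a %in% surv & physical$protein_b %in% surv &
      physical$protein_a != physical$protein_b
    touching <- unique(c(physical$protein_a[in_net],
                         physical$protein_b[in_net]))
    physical_support <- tfs %in% touching
  }
  data.frame(gene = tfs,
             out_degree = as.integer(out_deg),
             in_degree = as.integer(in_deg),
             is_de = is_de,
             direction = direction,
             reciprocal = as.integer(non_self_out) > 0 &
               as.integer(non_self_in) > 0,
             physical_support = physical_support,
             stringsAsFactors = FALSE)
}

#' Split candidates into all vs differentially expressed master regulators
#'
#' @param candidates Candidate table from [annotate_candidates()].
#' @return List with `all_mrs` (every candidate) and `de_mrs` (the
#'   differentially expressed ones, carrying their direction).
#' @export
select_master_regulators <- function(candidates) {
  list(all_mrs = candidates,
       de_mrs = candidates[candidates$is_de, , drop = FALSE])
}
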