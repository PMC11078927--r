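# Reference-network assembly and expression-based contextualization.
#
# The reference gene regulatory network is the deduplicated union of one or
# more curated TF->target edge lists. Contextualization restricts it to a
# biological condition by deleting the outgoing edges of transcription
# factors that are not expressed there (mean raw count below a cutoff,
# 10 raw counts by default).

#' Construct a regulatory network object
#'
#' @param edges Edge data frame with columns `regulator`, `target`, `mode`,
#'   `sources`, `confidence` (at most one edge per ordered pair).
#' @param nodes Optional node data frame with columns `gene` and `is_tf`
#'   (the reference role flag: `TRUE` iff the gene has at least one outgoing
#'   edge in the reference network). Derived from `edges` when omitted.
#' @return Object of class `regulatory_network`: list with elements `edges`
#'   and `nodes`.
#' @export
regulatory_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (cc in c("mode", "sources", "confidence")) {
    if (is.null(edges[[cc]])) {
      edges[[cc]] <- if (cc == "mode") rep("unknown", nrow(edges)) else NA_character_
    }
  }
  edges <- edges[, c("regulator", "target", "mode", "sources", "confidence"),
                 drop = FALSE]
  key <- paste(edges$regulator, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    stop("regulatory network must be simple: duplicate edge ",
         edges$regulator[duplicated(key)][1], " -> ",
         edges$target[duplicated(key)][1], call. = FALSE)
  }
  if (is.null(nodes)) {
    gene <- sort(unique(c(edges$regulator, edges$target)))
    nodes <- data.frame(gene = gene,
                        is_tf = gene %in% edges$regulator,
                        stringsAsFactors = FALSE)
  } else {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    miss <- setdiff(unique(c(edges$regulator, edges$target)), nodes$gene)
    if (length(miss) > 0) {
      stop("edge endpoint missing from node table: ", miss[1], call. = FALSE)
    }
  }
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d nodes (%d TFs), %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_tf), nrow(x$edges)))
  invisible(x)
}

#' Build the reference network as the union of edge lists
#'
#' Edges sharing an ordered (regulator, target) pair are merged: provenance
#' sets are unioned, and conflicting regulation modes (activation in one
#' database, repression in another) become `ambiguous`; `unknown` never
#' overrides an informative mode. Duplicate identical rows collapse
#' silently. Self-loops are retained.
#'
#' @param edge_lists A list of edge data frames (each as returned by
#'   [read_edge_list()]), or a single edge data frame.
#' @return A [regulatory_network] with canonically ordered (regulator,
#'   target) edges.
#' @export
build_reference_network <- function(edge_lists) {
  if (is.data.frame(edge_lists)) edge_lists <- list(edge_lists)
  edge_lists <- Filter(function(e) nrow(e) > 0, edge_lists)
  if (length(edge_lists) == 0) {
    stop("cannot build a reference network: all edge lists are empty",
         call. = FALSE)
  }
  all <- do.call(rbind, lapply(edge_lists, function(e) {
    e <- as.data.frame(e, stringsAsFactors = FALSE)
    if (is.null(e$confidence)) e$confidence <- NA_character_
    e[, c("regulator", "target", "mode", "sources", "confidence"),
      drop = FALSE]
  }))
  key <- paste(all$regulator, all$target, sep = "\r")
  groups <- split(seq_len(nrow(all)), key)
  merged <- lapply(groups, function(i) {
    modes <- unique(all$mode[i])
    informative <- setdiff(modes, "unknown")
    mode <- if ("ambiguous" %in% informative ||
                all(c("activation", "repression") %in% informative)) {
      "ambiguous"
    } else if (length(informative) == 1) {
      informative
    } else {
      "unknown"
    }
    src <- sort(unique(unlist(strsplit(all$sources[i], ";", fixed = TRUE))))
    conf <- sort(unique(all$confidence[i][!is.na(all$confidence[i])]))
    data.frame(regulator = all$regulator[i[1]], target = all$target[i[1]],
               mode = mode, sources = paste(src, collapse = ";"),
               confidence = if (length(conf) > 0) paste(conf, collapse = ";") else NA_character_,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, merged)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  regulatory_network(edges)
}

#' Per-gene expression status in one condition
#'
#' A gene is called expressed when the aggregate of its raw counts over the
#' condition's samples reaches the cutoff `tau` (boundary inclusive). The
#' aggregate is the arithmetic mean by default; raw, not normalized, counts
#' are used.
#'
#' @param cm A [count_matrix].
#' @param condition Condition label to aggregate over (`"control"` or
#'   `"case"`).
#' @param tau Expression cutoff in raw counts (default 10).
#' @param aggregate How to aggregate replicate counts: `"mean"` (default),
#'   `"min"` or `"max"`.
#' @return Data frame with columns `gene`, `mean_raw_count` (the aggregate)
#'   and `expressed`.
#' @export
expression_status <- function(cm, condition, tau = 10,
                              aggregate = c("mean", "min", "max")) {
  stopifnot(inherits(cm, "count_matrix"))
  aggregate <- match.arg(aggregate)
  idx <- which(cm$sample_meta$condition == condition)
  if (length(idx) == 0) {
    stop("no samples with condition '", condition, "'", call. = FALSE)
  }
  sub <- cm$counts[, idx, drop = FALSE]
  agg <- switch(aggregate,
                mean = rowMeans(sub),
                min = apply(sub, 1, min),
                max = apply(sub, 1, max))
  data.frame(gene = rownames(cm$counts), mean_raw_count = unname(agg),
             expressed = unname(agg >= tau), stringsAsFactors = FALSE)
}

#' Contextualize a reference network to an expression status
#'
#' Removes every outgoing edge of a non-expressed transcription factor
#' (genes absent from the status table count as not expressed). Incoming
#' edges of a gene are retained regardless of its own expression. Nodes left
#' without any edge are dropped; the result's edge set is a subset of the
#' reference's, and the operation is idempotent.
#'
#' @param ref A [regulatory_network].
#' @param status Expression status table from [expression_status()].
#' @return A contextualized [regulatory_network]; node `is_tf` flags keep
#'   their reference meaning.
#' @export
contextualize <- function(ref, status) {
  stopifnot(inherits(ref, "regulatory_network"))
  expressed <- status$gene[status$expressed]
  keep <- ref$edges$regulator %in% expressed
  edges <- ref$edges[keep, , drop = FALSE]
  present <- unique(c(edges$regulator, edges$target))
  nodes <- ref$nodes[ref$nodes$gene %in% present, , drop = FALSE]
  regulatory_network(edges, nodes)
}
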