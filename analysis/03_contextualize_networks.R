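#!/usr/bin/env Rscript
# Stage 3: per-condition contextualization of the reference network.
#
# A TF counts as expressed in a condition when its mean raw count over that
# condition's replicates reaches 10; outgoing edges of silent TFs are
# removed, incoming edges are kept, and stranded degree-0 nodes drop out.

library(masterreg)

cm <- read_count_matrix("results/synthetic/counts.tsv",
                        "results/synthetic/samples.tsv")
ref <- build_reference_network(
  read_edge_list("results/synthetic/reference_edges.tsv", "generic3col"))
dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)

cat(sprintf("reference: %d nodes, %d edges\n", nrow(ref$nodes), nrow(ref$edges)))
for (cond in c("control", "case")) {
  status <- expression_status(cm, cond, tau = 10)
  ctx <- contextualize(ref, status)
  write_edge_list(ctx$edges, sprintf("results/networks/context_%s.tsv", cond))
  write_network_graphml(ctx, sprintf("results/networks/context_%s.graphml", cond))
  silenced <- sum(ref$nodes$is_tf) -
    sum(status$expressed[status$gene %in% ref$nodes$gene[ref$nodes$is_tf]])
  cat(sprintf("[%s] %d of %d TFs below the cutoff; contextualized: %d nodes, %d edges\n",
              cond, silenced, sum(ref$nodes$is_tf),
              nrow(ctx$nodes), nrow(ctx$edges)))
}
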