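#!/usr/bin/env Rscript
# Stage 4: master regulator inference.
#
# For each condition's contextualized network: induce the first/second
# upstream neighborhood of the DEGs, prune iteratively by lowest
# out-degree under the weak-connectivity guard, annotate the surviving
# TFs (degrees, DE status, reciprocity), and keep the differentially
# expressed survivors. The headline set is the intersection across
# conditions; recovery against the planted truth is reported.

library(masterreg)

de <- read.delim("results/de/de_colon.tsv", stringsAsFactors = FALSE)
degs <- de$gene_id[de$status %in% c("up", "down")]
truth <- jsonlite::read_json("results/synthetic/truth.json",
                             simplifyVector = TRUE)
dir.create("results/mr", showWarnings = FALSE, recursive = TRUE)

de_sets <- list()
for (cond in c("control", "case")) {
  edges <- read_edge_list(sprintf("results/networks/context_%s.tsv", cond),
                          "generic3col")
  ctx <- build_reference_network(edges)
  neigh <- suppressWarnings(upstream_neighborhood(ctx, degs))
  pruned <- iterative_core_pruning(neigh)
  cand <- annotate_candidates(pruned$survivors, de)
  sel <- select_master_regulators(cand)
  write.table(pruned$trace, sprintf("results/mr/trace_%s.tsv", cond),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cand, sprintf("results/mr/candidates_%s.tsv", cond),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_network_graphml(
    pruned$survivors, sprintf("results/mr/mr_network_%s.graphml", cond),
    node_attrs = data.frame(gene = cand$gene, direction = cand$direction,
                            is_DE = cand$is_de))
  de_sets[[cond]] <- sel$de_mrs$gene
  cat(sprintf("[%s] neighborhood %d nodes -> %d survivors; %d TF candidates, %d differentially expressed (%s)\n",
              cond, nrow(neigh$nodes), nrow(pruned$survivors$nodes),
              nrow(sel$all_mrs), nrow(sel$de_mrs),
              paste(sel$de_mrs$gene, collapse = ", ")))
}

headline <- sort(Reduce(intersect, de_sets))
cat(sprintf("\nDE master regulators in both conditions: %s\n",
            paste(headline, collapse = ", ")))
cat(sprintf("planted truth: %s\n", paste(truth$planted_mrs, collapse = ", ")))
cat(sprintf("recovered %d of %d planted MRs, %d false positives\n",
            length(intersect(headline, truth$planted_mrs)),
            length(truth$planted_mrs),
            length(setdiff(headline, truth$planted_mrs))))
writeLines(headline, "results/mr/de_master_regulators.txt")
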