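#!/usr/bin/env Rscript
# Stage 1: generate the planted-truth study data.
#
# Emulates the experimental design the pipeline targets: two conditions
# (control vs case) with 4 replicates each, a curated-style reference
# TF->target network of 30 TFs and 300 targets in which 5 planted master
# regulators form a reciprocal hub clique, and a qPCR counter-sample of the
# planted MRs. Everything is written as plain TSV/JSON under
# results/synthetic/.

library(masterreg)

scenario <- synthetic_scenario(seed = 1)
paths <- write_synthetic_scenario(scenario, "results/synthetic")

truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
cm <- read_count_matrix(paths$counts, paths$meta)
net <- build_reference_network(read_edge_list(paths$edges, "generic3col"))

cat("Synthetic study written to results/synthetic/\n")
cat(sprintf("  counts: %d genes x %d samples (%d replicates/condition)\n",
            nrow(cm$counts), ncol(cm$counts), scenario$n_replicates))
cat(sprintf("  reference network: %d nodes (%d TFs), %d edges\n",
            nrow(net$nodes), sum(net$nodes$is_tf), nrow(net$edges)))
cat(sprintf("  planted master regulators: %s\n",
            paste(truth$planted_mrs, collapse = ", ")))
cat(sprintf("  TFs forced below the expression cutoff in the case condition: %s\n",
            paste(truth$low_expressed_tfs, collapse = ", ")))
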