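#!/usr/bin/env Rscript
# Stage 5: overrepresentation of the DEG set.
#
# With no external GO annotation in the synthetic setting, the natural
# gene-set collection is the reference network's regulons (the target set
# of each TF): the regulons of the planted master regulators should be the
# enriched ones, exactly as pathway terms would be on real data.

library(masterreg)

de <- read.delim("results/de/de_colon.tsv", stringsAsFactors = FALSE)
degs <- de$gene_id[de$status %in% c("up", "down")]
universe <- de$gene_id[!is.na(de$p)]
edges <- read_edge_list("results/synthetic/reference_edges.tsv", "generic3col")
truth <- jsonlite::read_json("results/synthetic/truth.json",
                             simplifyVector = TRUE)

regulons <- lapply(split(edges$target, edges$regulator), unique)
sets <- lapply(names(regulons), function(tf) {
  list(term_name = sprintf("regulon of %s", tf), genes = regulons[[tf]])
})
names(sets) <- names(regulons)

res <- overrepresentation_test(degs, sets, universe,
                               min_size = 5, max_size = 500)
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
write.table(res, "results/enrichment/regulon_enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

hits <- res$term_id[res$padj < 0.05]
cat(sprintf("%d of %d regulons enriched at padj < 0.05: %s\n",
            length(hits), nrow(res), paste(hits, collapse = ", ")))
cat(sprintf("planted MR regulons among them: %d of %d\n",
            length(intersect(hits, truth$planted_mrs)),
            length(truth$planted_mrs)))
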