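#!/usr/bin/env Rscript
# Stage 2: differential expression, case vs control.
#
# Size factors by median-of-ratios, per-gene method-of-moments NB
# dispersion, Wald test on the log2 fold change, BH adjustment, and
# up/down calls at adjusted p < 0.05 (no fold-change filter for the set
# fed to the network stage; a |log2FC| > 2 volcano-style filter is
# reported alongside for comparison).

library(masterreg)

cm <- read_count_matrix("results/synthetic/counts.tsv",
                        "results/synthetic/samples.tsv")
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)

for (tissue in sort(unique(cm$sample_meta$tissue))) {
  de <- run_de(cm, tissue = tissue, thresholds = de_thresholds(alpha = 0.05))
  out <- sprintf("results/de/de_%s.tsv", tissue)
  write.table(de$table, out, sep = "\t", quote = FALSE, row.names = FALSE)
  strict <- classify_degs(de$table, de_thresholds(0.05, fc_threshold = 2))
  cat(sprintf("[%s] %d genes tested: %d up, %d down at padj < 0.05 (-> %s)\n",
              tissue, de$summary$n_tested, de$summary$n_up,
              de$summary$n_down, out))
  cat(sprintf("[%s] with the |log2FC| > 2 reporting filter: %d up, %d down\n",
              tissue, strict$summary$n_up, strict$summary$n_down))
}
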