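---
title: "Master regulator discovery from contextualized regulatory networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Master regulator discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masterreg)
```

## The problem

In chronic inflammatory disease, the pathological phenotype of a cell
population — here the motivating case is effector CD4+ T cells in gut
inflammation — is rarely explained by any single differentially expressed
gene. A small number of transcription factors at the top of the regulatory
hierarchy can coordinate the expression of many downstream genes at once;
these are the *master regulators*. `masterreg` implements a topological
(not activity-score-based) master regulator definition: a TF that remains
in the densest core of the regulatory neighborhood of the differentially
expressed genes, directing and being directed by other such TFs.

The workflow is: differential expression on a count matrix → assembly and
per-condition contextualization of a curated reference TF→target network →
induction of the DEGs' upstream neighborhood → iterative lowest-out-degree
pruning → annotation and selection of differentially expressed survivors.

## Differential expression model

Counts for gene $g$ in sample $j$ are modeled as negative binomial with
mean $s_j q_{gc(j)}$ and variance $\mu + \alpha_g \mu^2$, where $s_j$ is a
median-of-ratios size factor and $c(j)$ the sample's condition.

* **Size factors.** $s_j = \mathrm{median}_g\, K_{gj} / (\prod_k K_{gk})^{1/m}$
  over reference genes with strictly positive counts in all samples. If no
  such gene exists the estimator refuses (no hidden pseudo-reference
  fallback). This estimator assumes that most genes are unchanged and that
  changes are not overwhelmingly one-sided; a strongly one-sided DE
  composition shifts the two conditions' medians apart and biases *every*
  null fold change (see Limitations).
* **Dispersion.** Per gene, the moment estimator
  $\hat\alpha_c = (v_c - m_c)/m_c^2$ on normalized counts within each
  condition, pooled across conditions weighted by $n_c - 1$, floored at
  $10^{-8}$ when the variance does not exceed the mean (Poisson-like or
  constant genes). No dispersion trend, shrinkage, independent filtering or
  outlier handling is attempted — this is a deliberately transparent
  simplification, adequate for the topological use the DE calls are put to.
* **Wald test.** Group means $q_c$ are means of normalized counts plus a
  pseudocount of 0.5 (which keeps fold changes finite for zero groups
  without shrinkage machinery, and is also used in the information so that
  an all-zero group yields a finite, conservative standard error);
  $\log_2 FC = \log_2 (q_{case}+0.5) - \log_2 (q_{ctrl}+0.5)$, with
  $\mathrm{Var}(\ln q_c) = 1 / \sum_{j \in c} \mu_j/(1+\alpha\mu_j)$ at the
  fitted means. The statistic is referred to a standard normal (the usual
  Wald contract), so p-values are asymptotic: at 50 replicates per group
  the null rejection rate at 0.05 is ≈ 0.05, while at 4 replicates it is
  ≈ 0.08–0.09 — anti-conservative, as expected for a plug-in Wald test at
  small $n$. Genes with zero counts in both groups are reported `untested`
  rather than given degenerate values.
* **Calls.** BH adjustment excludes untested genes from the number of
  tests. The DEG set handed to the network stage uses `padj < 0.05` with no
  fold-change filter; a volcano-style $|\log_2 FC| > 2$ filter is available
  (`fc_threshold`) and used only in reporting, since the network stage is
  defined on "differentially expressed genes" generally.

## Network assembly and contextualization

The reference network is the union of the supplied edge lists. Parsing is
lossless (self-loops and duplicate rows are kept) and merging happens once,
at union time: one edge per ordered (regulator, target) pair, provenance
sets unioned, activation-vs-repression conflicts across databases marked
`ambiguous`, `unknown` never overriding an informative mode. Gene symbols
are opaque and case-sensitive; no identifier mapping is attempted.

Contextualization removes the outgoing edges of TFs not expressed in a
condition. "Expressed" is the arithmetic mean of *raw* counts over the
condition's replicates reaching $\tau = 10$, boundary inclusive. The mean
is the least surprising aggregate for a per-condition network, but because
nothing in the definition forces it, the aggregation is configurable
(`mean`, `min`, `max`). Incoming edges of a silent gene are kept — a gene
that is off can still be a (vacuous) target — and nodes stranded with
degree 0 are dropped. The operation is by construction idempotent and
monotone in $\tau$, and the test suite verifies it against the one-line
brute-force filter it must equal.

## Neighborhood induction and core pruning

From each contextualized network the pipeline keeps the DEGs present in it
plus every node with a directed path of length 1 or 2 *to* a DEG (first and
second upstream neighbors), with all edges among the retained nodes.

The core extraction then iterates: remove the node with the minimal current
out-degree; if the remainder would be weakly disconnected or have fewer
than two nodes, undo and stop. Conventions the procedure needs but that a
verbal description leaves open were fixed as follows, and the pruning trace
exposes every step so alternatives can be compared:

* **"Unconnected" = weak disconnection** of the directed graph — the
  standard reading for regulatory maps, where an edge in either direction
  keeps two genes in the same regulatory context. A remainder of fewer than
  two nodes also stops the procedure, making termination well defined.
* **Tie-breaking** at equal out-degree: minimal in-degree, then
  lexicographic node id. This makes the algorithm fully deterministic; the
  suite checks exact survivor-set and trace equality against an
  independently coded igraph-based oracle on 200 random graphs.
* **Stop at the first blocking removal** (the default): the first node
  whose removal would disconnect the network ends the procedure, rather
  than being skipped. A `skip_blockers = TRUE` variant that tries the
  next-lowest node prunes at least as deep and is provided for comparison.
* **Self-loops** count once toward out- and in-degree and never affect
  connectivity; they confer neither reciprocity nor physical support.
* **Disconnected inputs** are pruned per weak component (components
  ordered by their smallest node id) and the results merged — upstream
  neighborhoods of scattered DEG sets are routinely disconnected.
* **All nodes are removable, only reference TFs become candidates.** Pure
  targets have out-degree 0 and are removed first under the rule anyway.

Surviving reference TFs are annotated with their degrees inside the
survivor subgraph, reciprocity (≥ 1 outgoing and ≥ 1 incoming edge with
other survivors), optional physical-interaction support from a STRING-like
pair table (`NA` when none is supplied), and their own DE status. The
master regulators of a run are the differentially expressed survivors.
Because the procedure runs once per condition, the pipeline reports the
per-condition sets, their union and their intersection; the intersection is
the headline set, since a regulator of the contrast should be present — and
differentially expressed — in the regulatory context of both conditions,
and this also discards TFs whose network presence is an artifact of being
switched off in one condition.

## Enrichment and qPCR stages

Overrepresentation uses the exact hypergeometric upper tail (equivalently
one-sided Fisher), BH-adjusted across the tested terms. The universe
defaults to the genes actually tested for DE, not the whole annotation —
the standard guard against annotation-composition bias — and term sizes are
bounded to [5, 500] after intersection with the universe, common practice
where no principled value exists.

qPCR quantification is plain $2^{-\Delta\Delta Ct}$: $\Delta Ct$ against
the housekeeping gene, referenced to the *arithmetic mean of the control
group's* $\Delta Ct$, so the control mean relative expression is 1 and
plots match the usual normalized axis. Groups are compared with the
unpaired pooled-variance Student t-test ($df = n_x + n_y - 2$); zero pooled
variance returns $p = 1$ at equal means and a warned degenerate $p = 0$
otherwise. No amplification-efficiency correction is applied.

## The synthetic generator

`synthetic_scenario()` defines the study the test-bed emulates: a
two-condition (control/case) design with `n_replicates = 4` per condition —
the replicate number of the motivating experimental design — over
`n_tfs = 30` TFs and `n_targets = 300` targets, with `n_planted_mrs = 5`
master regulators, NB baseline mean 200 and dispersion 0.1 (typical
bulk-RNA-seq values at desk scale), `mr_log2fc = 1.5` on the MR transcripts
and `cascade_log2fc = 2` on their direct targets, and 20% of the non-MR TFs
forced below the expression cutoff in the case condition to exercise
contextual pruning.

Construction choices worth recording:

* Planted MRs are **hubs with 1.5× the ordinary mean out-degree** and form
  a complete reciprocal clique (so they satisfy the directing-and-directed
  property by construction). The hub factor is deliberately modest: with a
  much larger factor the planted regulons cover a third of the (small)
  transcriptome, which both stops being a "small set of drivers" and
  violates the composition assumption of median-of-ratios normalization,
  biasing every null fold change. Real studies have DE fractions of a few
  percent; the default scenario lands near 15%, already a stress test.
* **Cascade effects are signed by regulation mode**: activated targets go
  up with their master regulator, repressed targets down. This is the
  biologically coherent construction and keeps the DE composition roughly
  balanced.
* Effects multiply the NB **means** (counts stay properly NB distributed);
  low-expressed TFs draw a case mean uniformly in [2, 8], safely below the
  cutoff of 10.
* Determinism: the network generator seeds with `seed`, the count sampler
  with `seed + 1`, the qPCR sampler with its own seed argument; draw order
  is fixed, so identical scenarios reproduce bit-identically.

What the generator does **not** emulate: batch effects (the pipeline
accepts an externally batch-corrected matrix instead; no batch covariate is
modeled), library-size variation beyond what NB sampling induces, ambiguous
or versioned database content, gene-length or GC biases, and any read-level
artifacts. Passing the planted-truth tests therefore demonstrates the
correctness of the algorithms under their stated model, not robustness to
every failure mode of real data.

## Problem sizes used by the test suite and the acceptance script

Chosen as the smallest sizes at which each property is meaningfully
testable: 200 random directed graphs of ≤ 10 nodes for pruning-oracle
equivalence; the default 330-gene scenario over seeds 1–10 for
planted-MR recovery (median recovered and median false positives); 2000
genes × 50 replicates/condition for null calibration (the large-sample
regime where the normal Wald reference applies) and for the 10-seed FDR
mixture with sign-balanced 10% effects at $|\log_2 FC| = 2$; 100 random
network/expression fixtures for contextualization equivalence; and one
default-scenario double run for byte-identical determinism.

## Known limitations

* The Wald test is anti-conservative at very small replicate numbers
  (≈ 8–9% null rejections at $n = 4$); with the strong planted effects this
  costs little, but on real 4-replicate data the DEG list should be read
  accordingly (the motivating analyses face the same issue).
* Median-of-ratios normalization misbehaves when DE is abundant *and*
  one-sided; the generator avoids this regime by construction, and users
  with such data need spike-ins or control-gene normalization, which the
  package does not provide.
* The master regulator definition is purely topological. No
  activity/enrichment score (VIPER-style) is computed, so a TF whose
  targets change while its own transcript does not will appear among the
  surviving candidates but never in the DE master regulator set.
* Stop-at-first-block pruning is order-sensitive by design; the tie-break
  makes it reproducible, but a different (equally defensible) tie-break can
  yield a different survivor core. The trace is persisted precisely so such
  comparisons are possible.
* Gene identifiers are never mapped or corrected; inputs must share a
  symbol space.
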