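Package: masterreg
Title: Master Regulator Discovery from Bulk RNA-Seq via Contextualized
    Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies master regulator transcription factors driving a
    pathological condition from bulk RNA-seq count data. Implements a
    simplified negative-binomial Wald test for differential expression with
    Benjamini-Hochberg adjustment, builds a reference gene regulatory
    network as the deduplicated union of curated TF-target edge lists
    (TRRUST-, RegNetwork-, DoRothEA-style dialects), contextualizes it per
    condition by removing outgoing edges of non-expressed transcription
    factors, and extracts master regulator candidates by inducing the
    first/second upstream neighborhood of differentially expressed genes
    followed by iterative lowest-out-degree pruning with a connectivity
    guard. Includes hypergeometric overrepresentation analysis, delta-delta-Ct
    qPCR quantification, and a planted-truth synthetic data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
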