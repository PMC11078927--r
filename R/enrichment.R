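# Overrepresentation analysis of a gene list against a gene-set collection:
# exact hypergeometric upper-tail test per term, BH adjustment across the
# tested terms. Stands in for GO biological-process enrichment without any
# ontology topology handling.

#' Hypergeometric overrepresentation test
#'
#' Every term is first intersected with the universe and kept when its size
#' lies in `[min_size, max_size]`; the gene list is likewise restricted to
#' the universe. The per-term p-value is the exact hypergeometric upper
#' tail `P(X >= k)` for drawing `k` term genes in a list of `n` from a
#' universe of `N` containing `K` term genes (equivalently, one-sided
#' Fisher's exact test on the 2x2 table).
#'
#' @param degs Character vector: the gene list (typically the DEGs).
#' @param sets Gene-set collection from [read_gene_sets()].
#' @param universe Character vector of background genes (typically every
#'   gene tested for differential expression).
#' @param min_size,max_size Term-size bounds after intersection with the
#'   universe (defaults 5 and 500).
#' @return Data frame sorted by increasing p (ties by term id) with columns
#'   `term_id`, `term_name`, `k`, `n`, `K`, `N`, `p`, `padj`.
#' @export
overrepresentation_test <- function(degs, sets, universe,
                                    min_size = 5, max_size = 500) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("universe must be non-empty", call. = FALSE)
  degs <- intersect(unique(degs), universe)
  empty <- data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), padj = numeric(),
                      stringsAsFactors = FALSE)
  if (length(degs) == 0) return(empty)
  N <- length(universe)
  n <- length(degs)
  rows <- lapply(names(sets), function(tid) {
    genes <- intersect(sets[[tid]]$genes, universe)
    K <- length(genes)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(genes, degs))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, term_name = sets[[tid]]$term_name,
               k = k, n = n, K = K, N = N, p = p, padj = NA_real_,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(empty)
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$p)
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
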