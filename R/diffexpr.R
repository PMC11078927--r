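# Two-group differential expression on count data: median-of-ratios size
# factors, method-of-moments negative-binomial dispersion, a Wald test on
# the log fold change with a normal reference, and Benjamini-Hochberg
# adjustment. This is a deliberately simplified NB pipeline: no dispersion
# trend or shrinkage, no independent filtering, no outlier handling.

.DISPERSION_FLOOR <- 1e-8

#' Median-of-ratios size factors
#'
#' For each sample j, `s_j` is the median over reference genes g of
#' `counts[g, j] / geomean_k(counts[g, k])`, where the reference genes are
#' those with strictly positive counts in every sample.
#'
#' @param cm A [count_matrix].
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no gene has strictly positive counts in every sample; ",
         "size factors cannot be estimated (pseudo-reference fallback is disabled)",
         call. = FALSE)
  }
  loggeo <- rowMeans(log(counts[ref, , drop = FALSE]))
  apply(counts[ref, , drop = FALSE], 2,
        function(col) exp(stats::median(log(col) - loggeo)))
}

#' Method-of-moments per-gene NB dispersion
#'
#' On size-factor-normalized counts, computes within each condition the
#' moment estimate `alpha_c = (var - mean) / mean^2` and pools the
#' per-condition estimates weighted by their degrees of freedom
#' (`n_c - 1`). Genes whose pooled estimate is non-positive or undefined
#' (variance at or below the mean, zero mean) get the floor value `1e-8`.
#'
#' @param cm A [count_matrix].
#' @param sf Size factors from [estimate_size_factors()].
#' @param groups Character vector (named by sample or in column order)
#'   giving each sample's condition; every condition needs at least 2
#'   samples.
#' @return Named per-gene dispersion vector, floored at `1e-8`.
#' @export
estimate_dispersions <- function(cm, sf, groups) {
  stopifnot(inherits(cm, "count_matrix"))
  groups <- .match_groups(cm, groups)
  tabs <- table(groups)
  if (any(tabs < 2)) {
    stop("condition '", names(tabs)[tabs < 2][1],
         "' has fewer than 2 samples; dispersion cannot be estimated",
         call. = FALSE)
  }
  norm <- sweep(cm$counts, 2, sf, "/")
  acc_num <- rep(0, nrow(norm))
  acc_w <- rep(0, nrow(norm))
  for (g in names(tabs)) {
    idx <- which(groups == g)
    x <- norm[, idx, drop = FALSE]
    m <- rowMeans(x)
    v <- rowSums((x - m)^2) / (length(idx) - 1)
    a <- (v - m) / m^2
    ok <- is.finite(a)
    w <- length(idx) - 1
    acc_num[ok] <- acc_num[ok] + w * a[ok]
    acc_w[ok] <- acc_w[ok] + w
  }
  alpha <- ifelse(acc_w > 0, acc_num / acc_w, NA_real_)
  alpha[!is.finite(alpha) | alpha <= 0] <- .DISPERSION_FLOOR
  alpha <- pmax(alpha, .DISPERSION_FLOOR)
  names(alpha) <- rownames(cm$counts)
  alpha
}

# Internal: resolve a groups argument against the sample order of cm.
.match_groups <- function(cm, groups) {
  sid <- colnames(cm$counts)
  if (!is.null(names(groups))) {
    miss <- setdiff(sid, names(groups))
    if (length(miss) > 0) stop("no group for sample: ", miss[1], call. = FALSE)
    groups <- groups[sid]
  } else if (length(groups) != length(sid)) {
    stop("`groups` must have one entry per sample", call. = FALSE)
  }
  as.character(groups)
}

#' Negative-binomial Wald test for a two-group comparison
#'
#' Per gene, group means are fitted as means of size-factor-normalized
#' counts within each condition plus a 0.5 pseudocount (so that rescaling a
#' whole sample is absorbed by its size factor), the log2 fold change is
#' `log2(q_case / q_control)`, and
#' its standard error comes from the NB Fisher information at the fitted
#' means (`Var(ln q_c) = 1 / sum_j mu_j / (1 + alpha mu_j)` with
#' `mu_j = s_j q_c`). The Wald statistic is referred to a standard normal,
#' two-sided. Genes with zero counts in both groups are untested (`p` is
#' `NA`); no `NaN` is ever propagated.
#'
#' @param cm A [count_matrix].
#' @param sf Size factors.
#' @param disp Per-gene dispersions.
#' @param groups Sample conditions; exactly the two levels `"control"` and
#'   `"case"` must be present. Fold changes are case vs control.
#' @return Data frame (one row per gene) with columns `gene_id`,
#'   `base_mean`, `log2fc`, `dispersion`, `p`, `padj` (`NA`, to be filled by
#'   [bh_adjust()]) and `status` (`"untested"` placeholder).
#' @export
nb_wald_test <- function(cm, sf, disp, groups) {
  stopifnot(inherits(cm, "count_matrix"))
  groups <- .match_groups(cm, groups)
  lev <- sort(unique(groups))
  if (!identical(lev, c("case", "control"))) {
    stop("exactly the two conditions 'control' and 'case' must be present",
         call. = FALSE)
  }
  counts <- cm$counts
  disp <- disp[rownames(counts)]
  idx_c <- which(groups == "control")
  idx_t <- which(groups == "case")
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)

  q_ctl <- rowMeans(norm[, idx_c, drop = FALSE])
  q_cas <- rowMeans(norm[, idx_t, drop = FALSE])
  qc <- q_ctl + 0.5
  qt <- q_cas + 0.5
  log2fc <- log2(qt / qc)

  info_one <- function(q, idx) {
    mu <- outer(q, sf[idx])                 # genes x samples fitted means
    rowSums(mu / (1 + disp * mu))
  }
  var_ln <- 1 / info_one(qc, idx_c) + 1 / info_one(qt, idx_t)
  se_lfc <- sqrt(var_ln) / log(2)
  z <- log2fc / se_lfc
  p <- 2 * stats::pnorm(-abs(z))

  untested <- rowSums(counts[, c(idx_c, idx_t), drop = FALSE]) == 0
  log2fc[untested] <- NA_real_
  p[untested] <- NA_real_
  data.frame(gene_id = rownames(counts), base_mean = unname(base_mean),
             log2fc = unname(log2fc), dispersion = unname(disp),
             p = unname(p), padj = NA_real_,
             status = ifelse(untested, "untested", NA_character_),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Undefined entries (`NA`) are excluded from the number of tests `m` and
#' stay `NA`; adjusted values are monotone in rank and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Vector of BH-adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Differential-expression thresholds
#'
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param fc_threshold Absolute log2 fold-change cutoff (default 0: any
#'   significant gene counts as differentially expressed; the volcano-style
#'   reporting filter uses 2).
#' @return List of class `de_thresholds`.
#' @export
de_thresholds <- function(alpha = 0.05, fc_threshold = 0) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (fc_threshold < 0) stop("fc_threshold must be non-negative", call. = FALSE)
  structure(list(alpha = alpha, fc_threshold = fc_threshold),
            class = "de_thresholds")
}

#' Call up/down/ns status from an adjusted DE table
#'
#' A gene is `up` iff `padj < alpha` and `log2fc > fc_threshold`, `down`
#' symmetrically, otherwise `ns`; untested genes stay `untested`.
#'
#' @param det DE table with `padj` filled.
#' @param thresholds A [de_thresholds].
#' @return List with elements `table` (the DE table with `status` filled)
#'   and `summary` (list `n_up`, `n_down`, `n_tested`).
#' @export
classify_degs <- function(det, thresholds = de_thresholds()) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  if (all(is.na(det$padj)) && any(!is.na(det$p))) {
    stop("`padj` has not been filled; run bh_adjust() first", call. = FALSE)
  }
  status <- rep("ns", nrow(det))
  status[is.na(det$p)] <- "untested"
  sig <- !is.na(det$padj) & det$padj < thresholds$alpha
  status[sig & det$log2fc > thresholds$fc_threshold] <- "up"
  status[sig & det$log2fc < -thresholds$fc_threshold] <- "down"
  det$status <- status
  list(table = det,
       summary = list(n_up = sum(status == "up"),
                      n_down = sum(status == "down"),
                      n_tested = sum(!is.na(det$p))))
}

#' Run the whole differential-expression stage
#'
#' Convenience wrapper: optional tissue subset, size factors, dispersions,
#' Wald test, BH adjustment and status calls.
#'
#' @param cm A [count_matrix]; sample conditions are taken from its
#'   metadata.
#' @param tissue Optional tissue to subset to before testing.
#' @param thresholds A [de_thresholds].
#' @return List with `table`, `summary`, `size_factors`.
#' @export
run_de <- function(cm, tissue = NULL, thresholds = de_thresholds()) {
  if (!is.null(tissue)) cm <- subset_samples(cm, tissue = tissue)
  groups <- stats::setNames(cm$sample_meta$condition, cm$sample_meta$sample_id)
  sf <- estimate_size_factors(cm)
  disp <- estimate_dispersions(cm, sf, groups)
  det <- nb_wald_test(cm, sf, disp, groups)
  det$padj <- bh_adjust(det$p)
  res <- classify_degs(det, thresholds)
  res$size_factors <- sf
  res
}

#' Subset a count matrix by sample metadata
#'
#' @param cm A [count_matrix].
#' @param tissue,condition Optional filters; samples must match all given
#'   values.
#' @return A [count_matrix] restricted to the matching samples.
#' @export
subset_samples <- function(cm, tissue = NULL, condition = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- rep(TRUE, nrow(cm$sample_meta))
  if (!is.null(tissue)) keep <- keep & cm$sample_meta$tissue %in% tissue
  if (!is.null(condition)) keep <- keep & cm$sample_meta$condition %in% condition
  if (!any(keep)) stop("no samples match the requested subset", call. = FALSE)
  count_matrix(cm$counts[, keep, drop = FALSE],
               cm$sample_meta[keep, , drop = FALSE])
}
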