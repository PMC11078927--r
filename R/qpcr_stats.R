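# qPCR quantification by the delta-delta-Ct method (relative expression
# 2^-ddCt against a housekeeping gene, referenced to the control-group mean
# delta Ct) and the pooled-variance unpaired Student t-test used to compare
# the two groups.

#' Delta-delta-Ct relative expression
#'
#' Per animal: `dCt = Ct_target - Ct_housekeeping`; `ddCt = dCt - mean
#' control dCt` (arithmetic mean, so the control-group mean relative
#' expression is 1 by construction); `rq = 2^(-ddCt)`. Animals lacking a
#' housekeeping Ct are excluded with a warning.
#'
#' @param table qPCR Ct table (`animal_id`, `group`, `gene`, `ct`), e.g.
#'   from [read_qpcr_table()] or [simulate_qpcr()].
#' @param housekeeping Housekeeping gene symbol (e.g. `"Gapdh"`).
#' @param target Target gene symbol.
#' @return Data frame per animal with columns `animal_id`, `group`, `gene`,
#'   `dct`, `ddct`, `rq`.
#' @export
ddct_relative_expression <- function(table, housekeeping, target) {
  tgt <- table[table$gene == target, , drop = FALSE]
  if (nrow(tgt) == 0) stop("no Ct values for target '", target, "'",
                           call. = FALSE)
  hk <- table[table$gene == housekeeping, , drop = FALSE]
  m <- match(tgt$animal_id, hk$animal_id)
  if (anyNA(m)) {
    drop <- tgt$animal_id[is.na(m)]
    warning("excluding animal(s) without housekeeping Ct: ",
            paste(drop, collapse = ", "), call. = FALSE)
    tgt <- tgt[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  dct <- tgt$ct - hk$ct[m]
  ctl <- tgt$group == "control"
  if (!any(ctl)) stop("no control animals with both target and housekeeping Ct",
                      call. = FALSE)
  ddct <- dct - mean(dct[ctl])
  data.frame(animal_id = tgt$animal_id, group = tgt$group, gene = target,
             dct = dct, ddct = ddct, rq = 2^(-ddct),
             stringsAsFactors = FALSE)
}

#' Unpaired two-sided Student t-test (pooled variance)
#'
#' `df = n_x + n_y - 2`. Degenerate inputs with zero pooled variance give
#' `p = 1` when the means are equal and `p = 0` (with a warning) when they
#' differ.
#'
#' @param x,y Numeric vectors, at least 2 values each.
#' @return List with elements `t`, `df`, `p`.
#' @export
two_group_ttest <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("need at least 2 values per group", call. = FALSE)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (delta == 0) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means: degenerate t-test",
            call. = FALSE)
    return(list(t = sign(delta) * Inf, df = df, p = 0))
  }
  t <- delta / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Relative-expression analysis of a qPCR table
#'
#' Runs [ddct_relative_expression()] for each target and compares the
#' groups' relative expression with [two_group_ttest()].
#'
#' @param table qPCR Ct table.
#' @param housekeeping Housekeeping gene symbol.
#' @param targets Target gene symbols; defaults to every non-housekeeping
#'   gene in the table.
#' @return List with `per_animal` (stacked per-animal relative expression)
#'   and `summary` (per gene: group means, SEM, t, df, p).
#' @export
qpcr_analysis <- function(table, housekeeping = "Gapdh", targets = NULL) {
  if (is.null(targets)) {
    targets <- sort(setdiff(unique(table$gene), housekeeping))
  }
  per_animal <- do.call(rbind, lapply(targets, function(g) {
    ddct_relative_expression(table, housekeeping, g)
  }))
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  summary <- do.call(rbind, lapply(targets, function(g) {
    r <- per_animal[per_animal$gene == g, , drop = FALSE]
    ctl <- r$rq[r$group == "control"]
    cas <- r$rq[r$group == "case"]
    tt <- two_group_ttest(cas, ctl)
    data.frame(gene = g,
               mean_rq_control = mean(ctl), sem_rq_control = sem(ctl),
               mean_rq_case = mean(cas), sem_rq_case = sem(cas),
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  }))
  list(per_animal = per_animal, summary = summary)
}
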