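# End-to-end orchestration: read inputs, call DEGs per tissue, contextualize
# the reference network per condition, infer master regulators, run
# enrichment and qPCR analyses, and persist every intermediate plus a
# machine-readable report. Identical config and inputs give byte-identical
# tabular outputs; no timestamps are written.

#' Assemble and validate a pipeline configuration
#'
#' @param counts,meta Paths to the count-matrix and sample-metadata TSVs.
#' @param edges Data frame with columns `path` and `dialect` (one row per
#'   edge list), or a character vector of paths (then `dialect` applies to
#'   all).
#' @param dialect Default dialect when `edges` is a character vector.
#' @param gmt,physical,qpcr Optional paths: gene sets (GMT),
#'   physical-interaction pairs, qPCR Ct table.
#' @param alpha,fc_threshold DE thresholds (see [de_thresholds()]).
#' @param tau,tau_aggregate Expression cutoff and replicate aggregation for
#'   contextualization (see [expression_status()]).
#' @param min_term_size,max_term_size Enrichment term-size bounds.
#' @param housekeeping Housekeeping gene for the qPCR stage.
#' @param skip_blockers Pruning variant flag (see
#'   [iterative_core_pruning()]).
#' @param seed Integer recorded in the provenance block (the pipeline itself
#'   is deterministic given its inputs).
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, meta, edges, dialect = "generic3col",
                            gmt = NULL, physical = NULL, qpcr = NULL,
                            alpha = 0.05, fc_threshold = 0,
                            tau = 10, tau_aggregate = "mean",
                            min_term_size = 5, max_term_size = 500,
                            housekeeping = "Gapdh",
                            skip_blockers = FALSE, seed = 1L,
                            out_dir = "masterreg_out") {
  if (is.character(edges)) {
    edges <- data.frame(path = edges, dialect = dialect,
                        stringsAsFactors = FALSE)
  }
  cfg <- list(counts = counts, meta = meta, edges = edges, gmt = gmt,
              physical = physical, qpcr = qpcr, alpha = alpha,
              fc_threshold = fc_threshold, tau = tau,
              tau_aggregate = tau_aggregate, min_term_size = min_term_size,
              max_term_size = max_term_size, housekeeping = housekeeping,
              skip_blockers = isTRUE(skip_blockers),
              seed = as.integer(seed), out_dir = out_dir)
  for (field in c("counts", "meta")) {
    if (!file.exists(cfg[[field]])) {
      stop("config field '", field, "': file not found: ", cfg[[field]],
           call. = FALSE)
    }
  }
  for (i in seq_len(nrow(cfg$edges))) {
    if (!file.exists(cfg$edges$path[i])) {
      stop("config field 'edges': file not found: ", cfg$edges$path[i],
           call. = FALSE)
    }
  }
  for (field in c("gmt", "physical", "qpcr")) {
    if (!is.null(cfg[[field]]) && !file.exists(cfg[[field]])) {
      stop("config field '", field, "': file not found: ", cfg[[field]],
           call. = FALSE)
    }
  }
  de_thresholds(alpha, fc_threshold)  # range validation
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

# Internal: write a data frame as TSV with stable formatting.
.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full master-regulator discovery pipeline
#'
#' Stages, per tissue found in the metadata: differential expression
#' (NB Wald + BH); per condition, expression status and network
#' contextualization, first/second upstream neighborhood of the DEGs,
#' iterative core pruning, candidate annotation and master-regulator
#' selection; then the cross-condition intersection of the differentially
#' expressed master regulators (the headline set), optional
#' overrepresentation analysis of the DEGs, and optional qPCR
#' quantification. Every intermediate is persisted under `config$out_dir`
#' before the report is written.
#'
#' @param config A [pipeline_config].
#' @return The run report (list), invisibly also written as
#'   `report.json`/`summary.txt`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "read_inputs"
  report <- list()
  tryCatch({
    cm <- read_count_matrix(config$counts, config$meta)
    edge_lists <- lapply(seq_len(nrow(config$edges)), function(i) {
      read_edge_list(config$edges$path[i], dialect = config$edges$dialect[i])
    })
    ref <- build_reference_network(edge_lists)
    sets <- if (!is.null(config$gmt)) read_gene_sets(config$gmt) else NULL
    physical <- if (!is.null(config$physical)) read_physical_pairs(config$physical) else NULL
    qpcr_tab <- if (!is.null(config$qpcr)) read_qpcr_table(config$qpcr) else NULL

    thresholds <- de_thresholds(config$alpha, config$fc_threshold)
    tissues <- sort(unique(cm$sample_meta$tissue))
    report$reference_network <- list(n_nodes = nrow(ref$nodes),
                                     n_tfs = sum(ref$nodes$is_tf),
                                     n_edges = nrow(ref$edges))
    report$tissues <- list()
    networks <- list()

    for (tis in tissues) {
      stage <- paste0("diffexpr[", tis, "]")
      cm_t <- subset_samples(cm, tissue = tis)
      de <- run_de(cm_t, thresholds = thresholds)
      .write_tsv(de$table, file.path(config$out_dir,
                                     sprintf("de_%s.tsv", tis)))
      degs <- de$table$gene_id[de$table$status %in% c("up", "down")]
      tis_report <- list(de_summary = de$summary)

      conds <- sort(unique(cm_t$sample_meta$condition))
      per_cond <- list()
      for (cond in conds) {
        stage <- paste0("contextualize[", tis, ",", cond, "]")
        status <- expression_status(cm_t, cond, tau = config$tau,
                                    aggregate = config$tau_aggregate)
        ctx <- contextualize(ref, status)
        write_edge_list(ctx$edges,
                        file.path(config$out_dir,
                                  sprintf("context_%s_%s_edges.tsv", tis, cond)))
        write_network_graphml(ctx,
                              file.path(config$out_dir,
                                        sprintf("context_%s_%s.graphml", tis, cond)))
        stage <- paste0("master_regulators[", tis, ",", cond, "]")
        degs_in_net <- intersect(degs, ctx$nodes$gene)
        if (length(degs_in_net) == 0) {
          per_cond[[cond]] <- list(
            context_nodes = nrow(ctx$nodes), context_edges = nrow(ctx$edges),
            note = "no differentially expressed gene occurs in the contextualized network",
            n_survivors = 0, all_mrs = character(), de_mrs = character())
          next
        }
        neigh <- suppressWarnings(upstream_neighborhood(ctx, degs))
        pruned <- iterative_core_pruning(neigh,
                                         skip_blockers = config$skip_blockers)
        .write_tsv(pruned$trace,
                   file.path(config$out_dir,
                             sprintf("trace_%s_%s.tsv", tis, cond)))
        cand <- annotate_candidates(pruned$survivors, de$table, physical)
        .write_tsv(cand,
                   file.path(config$out_dir,
                             sprintf("candidates_%s_%s.tsv", tis, cond)))
        sel <- select_master_regulators(cand)
        networks[[paste(tis, cond, sep = "_")]] <-
          list(survivors = pruned$survivors, candidates = cand,
               tissue = tis, condition = cond)
        per_cond[[cond]] <- list(
          context_nodes = nrow(ctx$nodes), context_edges = nrow(ctx$edges),
          neighborhood_nodes = nrow(neigh$nodes),
          n_survivors = nrow(pruned$survivors$nodes),
          all_mrs = sel$all_mrs$gene,
          de_mrs = sel$de_mrs$gene,
          de_mr_direction = stats::setNames(as.list(sel$de_mrs$direction),
                                            sel$de_mrs$gene))
      }
      tis_report$conditions <- per_cond
      de_sets <- lapply(per_cond, `[[`, "de_mrs")
      all_sets <- lapply(per_cond, `[[`, "all_mrs")
      tis_report$de_mrs_intersection <- sort(Reduce(intersect, de_sets))
      tis_report$de_mrs_union <- sort(Reduce(union, de_sets))
      tis_report$all_mrs_intersection <- sort(Reduce(intersect, all_sets))

      if (!is.null(sets) && length(degs) > 0) {
        stage <- paste0("enrichment[", tis, "]")
        universe <- de$table$gene_id[!is.na(de$table$p)]
        enr <- overrepresentation_test(degs, sets, universe,
                                       min_size = config$min_term_size,
                                       max_size = config$max_term_size)
        .write_tsv(enr, file.path(config$out_dir,
                                  sprintf("enrichment_%s.tsv", tis)))
        tis_report$enrichment <- list(
          n_terms_tested = nrow(enr),
          n_terms_significant = sum(enr$padj < config$alpha, na.rm = TRUE))
      }
      report$tissues[[tis]] <- tis_report
    }

    if (!is.null(qpcr_tab)) {
      stage <- "qpcr"
      qa <- qpcr_analysis(qpcr_tab, housekeeping = config$housekeeping)
      .write_tsv(qa$per_animal, file.path(config$out_dir, "qpcr_per_animal.tsv"))
      .write_tsv(qa$summary, file.path(config$out_dir, "qpcr_summary.tsv"))
      report$qpcr <- lapply(seq_len(nrow(qa$summary)), function(i) {
        as.list(qa$summary[i, , drop = FALSE])
      })
    }

    stage <- "report"
    inputs <- c(counts = config$counts, meta = config$meta,
                stats::setNames(config$edges$path,
                                paste0("edges_", seq_len(nrow(config$edges)))))
    report$provenance <- list(
      package = "masterreg",
      package_version = as.character(utils::packageVersion("masterreg")),
      r_version = R.version.string,
      seed = config$seed,
      config = .config_echo(config),
      input_md5 = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                          names(inputs))))
    attr(report, "networks") <- networks
    write_report(report, config$out_dir)
    invisible(report)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

# Internal: serializable echo of the thresholds and paths in a config.
.config_echo <- function(config) {
  list(counts = config$counts, meta = config$meta,
       edges = lapply(seq_len(nrow(config$edges)), function(i) {
         list(path = config$edges$path[i], dialect = config$edges$dialect[i])
       }),
       gmt = config$gmt, physical = config$physical, qpcr = config$qpcr,
       alpha = config$alpha, fc_threshold = config$fc_threshold,
       tau = config$tau, tau_aggregate = config$tau_aggregate,
       min_term_size = config$min_term_size,
       max_term_size = config$max_term_size,
       housekeeping = config$housekeeping,
       skip_blockers = config$skip_blockers)
}

#' Write the run report
#'
#' Emits `report.json` (machine-readable), `summary.txt` (human-readable)
#' and, per tissue and condition, `mr_network_<tissue>_<condition>.graphml`:
#' the surviving master-regulator network annotated per node with `is_DE`,
#' `direction` (up/down/none, mirroring the red/blue border encoding of the
#' figures) and `is_master_regulator`.
#'
#' @param report Report list from [run_pipeline()].
#' @param path Output directory.
#' @export
write_report <- function(report, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  networks <- attr(report, "networks")
  attr(report, "networks") <- NULL
  jsonlite::write_json(report, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(networks)) {
    blk <- networks[[nm]]
    cand <- blk$candidates
    nodes <- blk$survivors$nodes$gene
    m <- match(nodes, cand$gene)
    is_de <- rep(FALSE, length(nodes))
    direction <- rep("none", length(nodes))
    hit <- !is.na(m)
    is_de[hit] <- cand$is_de[m[hit]]
    direction[hit] <- cand$direction[m[hit]]
    annot <- data.frame(gene = nodes, is_DE = is_de, direction = direction,
                        is_master_regulator = hit, stringsAsFactors = FALSE)
    write_network_graphml(blk$survivors,
                          file.path(path, sprintf("mr_network_%s.graphml", nm)),
                          node_attrs = annot)
  }

  lines <- c("masterreg run summary", "=====================", "")
  rn <- report$reference_network
  lines <- c(lines, sprintf("Reference network: %d nodes (%d TFs), %d edges",
                            rn$n_nodes, rn$n_tfs, rn$n_edges), "")
  for (tis in names(report$tissues)) {
    tr <- report$tissues[[tis]]
    lines <- c(lines, sprintf("Tissue: %s", tis),
               sprintf("  DEGs: %d up, %d down (of %d tested)",
                       tr$de_summary$n_up, tr$de_summary$n_down,
                       tr$de_summary$n_tested))
    for (cond in names(tr$conditions)) {
      cc <- tr$conditions[[cond]]
      lines <- c(lines, sprintf(
        "  [%s] contextualized: %d nodes / %d edges; survivors: %d; MR candidates: %d; DE MRs: %d",
        cond, cc$context_nodes, cc$context_edges, cc$n_survivors,
        length(cc$all_mrs), length(cc$de_mrs)))
    }
    lines <- c(lines, sprintf("  DE master regulators (both conditions): %s",
                              if (length(tr$de_mrs_intersection) > 0)
                                paste(tr$de_mrs_intersection, collapse = ", ")
                              else "none"))
    if (!is.null(tr$enrichment)) {
      lines <- c(lines, sprintf("  Enriched terms: %d of %d tested",
                                tr$enrichment$n_terms_significant,
                                tr$enrichment$n_terms_tested))
    }
    lines <- c(lines, "")
  }
  if (!is.null(report$qpcr)) {
    lines <- c(lines, "qPCR relative expression (case vs control):")
    for (row in report$qpcr) {
      lines <- c(lines, sprintf("  %s: %.3f +/- %.3f vs %.3f +/- %.3f (p = %.4g)",
                                row$gene, row$mean_rq_case, row$sem_rq_case,
                                row$mean_rq_control, row$sem_rq_control,
                                row$p))
    }
  }
  writeLines(lines, file.path(path, "summary.txt"))
  invisible(NULL)
}
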