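# Planted-truth synthetic data: a reference TF->target network with known
# master regulators, matching two-condition negative-binomial count data,
# and qPCR Ct tables. The default scenario mirrors the 4-replicate,
# two-condition bulk RNA-seq design the pipeline is meant for, at desk
# scale: 30 TFs, 300 targets, 5 planted master regulators.
#
# Draw order is fixed and every generator is seeded explicitly, so all
# outputs are deterministic given the scenario seed (the network uses
# `seed`, counts use `seed + 1`).

#' Parameterize a synthetic scenario
#'
#' @param seed Integer seed; the generators derive their streams from it.
#' @param n_tfs Number of transcription factors in the reference network.
#' @param n_targets Number of non-TF target genes.
#' @param n_planted_mrs Number of planted master regulators (hub TFs forming
#'   a reciprocal clique).
#' @param targets_per_tf Mean out-degree of an ordinary TF; planted master
#'   regulators draw 1.5 times this mean (hub bias, kept modest so that the
#'   planted regulon stays a small fraction of the transcriptome).
#' @param n_replicates Replicates per condition (two conditions: control and
#'   case).
#' @param baseline_mean Negative-binomial mean of unaffected genes.
#' @param dispersion Shared NB dispersion alpha (variance = mu + alpha mu^2).
#' @param mr_log2fc Planted log2 fold change of master-regulator transcripts
#'   in the case condition.
#' @param cascade_log2fc Planted log2 fold change of the direct targets of
#'   active master regulators.
#' @param frac_low_expressed_tfs Fraction of TFs (drawn from the non-MR TFs)
#'   whose case-condition mean is forced below the expression cutoff of 10
#'   raw counts, to exercise contextual pruning.
#' @return Validated list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_tfs = 30L,
                               n_targets = 300L,
                               n_planted_mrs = 5L,
                               targets_per_tf = 8,
                               n_replicates = 4L,
                               baseline_mean = 200,
                               dispersion = 0.1,
                               mr_log2fc = 1.5,
                               cascade_log2fc = 2.0,
                               frac_low_expressed_tfs = 0.2) {
  sc <- list(seed = as.integer(seed), n_tfs = as.integer(n_tfs),
             n_targets = as.integer(n_targets),
             n_planted_mrs = as.integer(n_planted_mrs),
             targets_per_tf = targets_per_tf,
             n_replicates = as.integer(n_replicates),
             baseline_mean = baseline_mean, dispersion = dispersion,
             mr_log2fc = mr_log2fc, cascade_log2fc = cascade_log2fc,
             frac_low_expressed_tfs = frac_low_expressed_tfs)
  if (sc$n_planted_mrs > sc$n_tfs) {
    stop("n_planted_mrs must not exceed n_tfs", call. = FALSE)
  }
  if (sc$n_tfs < 1 || sc$n_targets < 1 || sc$n_replicates < 1) {
    stop("n_tfs, n_targets and n_replicates must be at least 1", call. = FALSE)
  }
  if (sc$dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  if (sc$baseline_mean <= 0) stop("baseline_mean must be positive", call. = FALSE)
  if (sc$targets_per_tf <= 0 || sc$targets_per_tf > sc$n_targets) {
    stop("targets_per_tf must lie in (0, n_targets]: a TF cannot regulate ",
         "more distinct targets than exist", call. = FALSE)
  }
  if (sc$frac_low_expressed_tfs < 0 || sc$frac_low_expressed_tfs > 1) {
    stop("frac_low_expressed_tfs must lie in [0, 1]", call. = FALSE)
  }
  class(sc) <- "synthetic_scenario"
  sc
}

#' Simulate a planted-truth reference regulatory network
#'
#' Each TF regulates a random set of targets; planted master regulators are
#' hubs (their expected out-degree is 1.5 times the ordinary mean) and
#' additionally regulate each other pairwise, so they satisfy the
#' directing-and-being-directed property by construction. Deterministic
#' given the scenario seed.
#'
#' @param scenario A [synthetic_scenario].
#' @return List with elements `network` (a [regulatory_network]) and `truth`
#'   (class `planted_truth`: planted MR symbols, expected DE genes, the
#'   low-expressed TF set, the reference edges, the full gene roster and the
#'   scenario).
#' @export
simulate_reference_grn <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed)
  tfs <- sprintf("TF%03d", seq_len(scenario$n_tfs))
  targets <- sprintf("G%04d", seq_len(scenario$n_targets))
  mrs <- sort(sample(tfs, scenario$n_planted_mrs))
  n_low <- min(round(scenario$frac_low_expressed_tfs * scenario$n_tfs),
               scenario$n_tfs - scenario$n_planted_mrs)
  low_tfs <- sort(sample(setdiff(tfs, mrs), n_low))

  rows <- vector("list", scenario$n_tfs + 1L)
  for (i in seq_along(tfs)) {
    tf <- tfs[i]
    lambda <- if (tf %in% mrs) 1.5 * scenario$targets_per_tf else scenario$targets_per_tf
    d <- stats::rpois(1, lambda)
    d <- max(1L, min(d, scenario$n_targets))
    tg <- sample(targets, d)
    mode <- sample(c("activation", "repression"), d, replace = TRUE,
                   prob = c(0.7, 0.3))
    rows[[i]] <- data.frame(regulator = tf, target = tg, mode = mode,
                            stringsAsFactors = FALSE)
  }
  if (length(mrs) > 1) {
    pairs <- expand.grid(regulator = mrs, target = mrs,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$regulator != pairs$target, , drop = FALSE]
    pairs$mode <- "activation"
    rows[[scenario$n_tfs + 1L]] <- pairs
  }
  edges <- do.call(rbind, rows)
  edges$sources <- "synthetic"
  edges$confidence <- NA_character_
  net <- build_reference_network(edges)

  first_neighbors <- unique(edges$target[edges$regulator %in% mrs])
  truth <- structure(list(
    planted_mrs = mrs,
    de_genes_expected = sort(unique(c(mrs, first_neighbors, low_tfs))),
    low_expressed_tfs = low_tfs,
    reference_edges = net$edges,
    genes = c(tfs, targets),
    scenario = scenario), class = "planted_truth")
  list(network = net, truth = truth)
}

#' Simulate two-condition negative-binomial counts under a planted truth
#'
#' Unaffected genes are NB(`baseline_mean`, `dispersion`) in both
#' conditions. In the case condition, planted master-regulator transcripts
#' are shifted by `mr_log2fc`, the non-MR direct targets of the planted MRs
#' by `cascade_log2fc` signed by the regulation mode (activated targets up,
#' repressed targets down; effects applied multiplicatively to the NB mean),
#' and the designated low-expressed TFs get a case mean drawn below 10 raw
#' counts. Deterministic given the scenario seed.
#'
#' @param scenario A [synthetic_scenario].
#' @param truth The matching `planted_truth` from [simulate_reference_grn()].
#' @return A [count_matrix] with `2 * n_replicates` samples (tissue
#'   `"colon"`, conditions `control`/`case`).
#' @export
simulate_counts <- function(scenario, truth) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(truth, "planted_truth"))
  if (!identical(truth$scenario$seed, scenario$seed)) {
    stop("truth was generated under a different scenario seed", call. = FALSE)
  }
  set.seed(scenario$seed + 1L)
  genes <- truth$genes
  n <- scenario$n_replicates
  samples <- c(sprintf("control_%d", seq_len(n)), sprintf("case_%d", seq_len(n)))
  cond <- rep(c("control", "case"), each = n)

  mu_control <- rep(scenario$baseline_mean, length(genes))
  names(mu_control) <- genes
  mu_case <- mu_control
  mu_case[truth$planted_mrs] <- scenario$baseline_mean * 2^scenario$mr_log2fc
  mr_edges <- truth$reference_edges[
    truth$reference_edges$regulator %in% truth$planted_mrs, , drop = FALSE]
  cascade <- setdiff(unique(mr_edges$target), truth$planted_mrs)
  # Direction of the cascade follows the regulation mode: targets of an
  # activating edge rise with their master regulator, repressed targets
  # fall; a target under conflicting modes rises.
  activated <- unique(mr_edges$target[mr_edges$mode != "repression"])
  sign <- ifelse(cascade %in% activated, 1, -1)
  mu_case[cascade] <- scenario$baseline_mean * 2^(sign * scenario$cascade_log2fc)
  if (length(truth$low_expressed_tfs) > 0) {
    mu_case[truth$low_expressed_tfs] <-
      stats::runif(length(truth$low_expressed_tfs), 2, 8)
  }

  mu <- cbind(matrix(mu_control, nrow = length(genes), ncol = n),
              matrix(mu_case, nrow = length(genes), ncol = n))
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = 1 / scenario$dispersion),
                   nrow = length(genes), ncol = 2L * n,
                   dimnames = list(genes, samples))
  meta <- data.frame(sample_id = samples, tissue = "colon",
                     condition = cond, batch = "b1",
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

#' Simulate a qPCR Ct table for the planted master regulators
#'
#' Emulates the validation design: per-animal Ct values for each planted MR
#' and the housekeeping gene (`Gapdh`), with the case-group target Ct
#' reduced by `mr_log2fc` cycles (one PCR cycle per log2 unit) plus optional
#' Gaussian noise. With `noise_sd = 0`, [ddct_relative_expression()]
#' recovers a fold change of exactly `2^mr_log2fc` for every case animal.
#'
#' @param truth A `planted_truth`.
#' @param n_control Control-group animals (>= 2).
#' @param n_case Case-group animals (>= 2).
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of per-well Gaussian Ct noise, in
#'   cycles (default 0.3).
#' @return Data frame `animal_id  group  gene  ct`.
#' @export
simulate_qpcr <- function(truth, n_control = 4L, n_case = 3L, seed = 1L,
                          noise_sd = 0.3) {
  stopifnot(inherits(truth, "planted_truth"))
  if (n_control < 2 || n_case < 2) {
    stop("need at least 2 animals per group", call. = FALSE)
  }
  set.seed(as.integer(seed))
  animals <- c(sprintf("ctrl_%d", seq_len(n_control)),
               sprintf("case_%d", seq_len(n_case)))
  group <- rep(c("control", "case"), c(n_control, n_case))
  genes <- c(truth$planted_mrs, "Gapdh")
  grid <- expand.grid(animal_id = animals, gene = genes,
                      stringsAsFactors = FALSE)
  grid$group <- group[match(grid$animal_id, animals)]
  base_ct <- ifelse(grid$gene == "Gapdh", 20, 25)
  shift <- ifelse(grid$gene != "Gapdh" & grid$group == "case",
                  truth$scenario$mr_log2fc, 0)
  grid$ct <- base_ct - shift + stats::rnorm(nrow(grid), 0, noise_sd)
  grid[, c("animal_id", "group", "gene", "ct"), drop = FALSE]
}

#' Write a full synthetic scenario to disk
#'
#' Convenience wrapper producing every input the pipeline consumes: counts
#' TSV, metadata TSV, reference edge list (generic3col dialect), planted
#' truth JSON and qPCR TSV.
#'
#' @param scenario A [synthetic_scenario].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_synthetic_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_reference_grn(scenario)
  cm <- simulate_counts(scenario, sim$truth)
  qp <- simulate_qpcr(sim$truth, seed = scenario$seed + 2L)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                meta = file.path(dir, "samples.tsv"),
                edges = file.path(dir, "reference_edges.tsv"),
                truth = file.path(dir, "truth.json"),
                qpcr = file.path(dir, "qpcr.tsv"))
  write_count_matrix(cm, paths$counts, paths$meta)
  write_edge_list(sim$network$edges, paths$edges)
  jsonlite::write_json(
    list(planted_mrs = sim$truth$planted_mrs,
         de_genes_expected = sim$truth$de_genes_expected,
         low_expressed_tfs = sim$truth$low_expressed_tfs,
         scenario = unclass(scenario)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  utils::write.table(qp, paths$qpcr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
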