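# Readers and writers for every external representation the pipeline touches.
# All tabular formats are TSV with a mandatory header row; gene identifiers
# are opaque, case-sensitive symbols and are never altered beyond whitespace
# stripping.

#' Construct a validated count matrix object
#'
#' Bundles a genes x samples matrix of non-negative integer read counts with
#' per-sample metadata. This is the entry point of the pipeline: all
#' downstream stages (size factors, differential expression, expression
#' cutoffs for network contextualization) consume this object.
#'
#' @param counts Integer matrix with row names (gene ids) and column names
#'   (sample ids). Values must be non-negative integers.
#' @param sample_meta Data frame with columns `sample_id`, `tissue`,
#'   `condition` (one of `"control"`, `"case"`) and `batch`; one row per
#'   column of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `sample_meta` (rows ordered to match the columns of `counts`).
#' @export
count_matrix <- function(counts, sample_meta) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  gid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(gid) || is.null(sid)) {
    stop("`counts` must have gene ids as row names and sample ids as column names",
         call. = FALSE)
  }
  dup <- gid[duplicated(gid)]
  if (length(dup) > 0) {
    stop("duplicate gene identifier: ", dup[1], call. = FALSE)
  }
  dup <- sid[duplicated(sid)]
  if (length(dup) > 0) {
    stop("duplicate sample identifier: ", dup[1], call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("count for gene '%s', sample '%s' is not a non-negative integer",
                 gid[bad[1, 1]], sid[bad[1, 2]]), call. = FALSE)
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max
  req <- c("sample_id", "tissue", "condition", "batch")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss) > 0) {
    stop("sample metadata is missing column: ", miss[1], call. = FALSE)
  }
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  absent <- setdiff(sid, sample_meta$sample_id)
  if (length(absent) > 0) {
    stop("no metadata record for sample: ", absent[1], call. = FALSE)
  }
  bad_cond <- setdiff(unique(sample_meta$condition), c("control", "case"))
  if (length(bad_cond) > 0) {
    stop("condition must be 'control' or 'case', got: ", bad_cond[1],
         call. = FALSE)
  }
  sample_meta <- sample_meta[match(sid, sample_meta$sample_id),
                             req, drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$sample_meta$tissue, x$sample_meta$condition)
  print(tab)
  invisible(x)
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' @param path TSV file whose first column (`gene_id`) holds gene ids and
#'   whose remaining columns hold integer counts, one column per sample.
#' @param meta_path TSV file with columns `sample_id`, `tissue`, `condition`,
#'   `batch`.
#' @return A [count_matrix]; column order follows the file order.
#' @export
read_count_matrix <- function(path, meta_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (ncol(tab) < 2) stop("count matrix file needs a gene_id column plus at least one sample column", call. = FALSE)
  gid <- trimws(tab[[1]])
  sid <- trimws(colnames(tab)[-1])
  raw <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid count '%s' for gene '%s', sample '%s'",
                 raw[bad[1, 1], bad[1, 2]], gid[bad[1, 1]], sid[bad[1, 2]]),
         call. = FALSE)
  }
  dimnames(num) <- list(gid, sid)
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character",
                            quote = "")
  for (cc in names(meta)) meta[[cc]] <- trimws(meta[[cc]])
  count_matrix(num, meta)
}

#' Write a count matrix and its sample metadata to TSV files
#'
#' Inverse of [read_count_matrix()]: writing then reading yields an equal
#' object.
#'
#' @param cm A [count_matrix].
#' @param path Output TSV for the counts.
#' @param meta_path Output TSV for the sample metadata.
#' @export
write_count_matrix <- function(cm, path, meta_path) {
  stopifnot(inherits(cm, "count_matrix"))
  out <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

# Column layouts of the supported edge-list dialects (header names).
.edge_dialects <- list(
  trrust      = c(regulator = "TF", target = "target", mode = "mode"),
  regnetwork  = c(regulator = "regulator", target = "target"),
  dorothea    = c(regulator = "TF", target = "target", confidence = "confidence",
                  mor = "mor"),
  generic3col = c(regulator = "regulator", target = "target", mode = "mode")
)

.normalize_mode <- function(x) {
  x <- tolower(trimws(x))
  out <- rep("unknown", length(x))
  out[x == "activation"] <- "activation"
  out[x == "repression"] <- "repression"
  out[x == "ambiguous"] <- "ambiguous"
  out
}

#' Read a TF-to-target edge list in one of the supported dialects
#'
#' Supported header layouts (TSV, header mandatory):
#' \describe{
#'   \item{trrust}{`TF  target  mode  PMIDs` (mode `Activation`/`Repression`/
#'     `Unknown`; unrecognized strings map to `unknown`)}
#'   \item{regnetwork}{`regulator  regulator_id  target  target_id` (mode is
#'     always `unknown`)}
#'   \item{dorothea}{`TF  confidence  target  mor` (sign of `mor` gives
#'     activation/repression; 0 or missing gives `unknown`)}
#'   \item{generic3col}{`regulator  target  mode`}
#' }
#' Parsing is lossless: self-loops and duplicate rows are preserved and
#' resolved later by [build_reference_network()].
#'
#' @param path TSV file.
#' @param dialect One of `"trrust"`, `"regnetwork"`, `"dorothea"`,
#'   `"generic3col"`.
#' @param source Provenance label recorded per edge; defaults to the dialect
#'   name.
#' @return Data frame of edge records with columns `regulator`, `target`,
#'   `mode` (`activation`/`repression`/`unknown`/`ambiguous`), `sources`
#'   (`;`-joined provenance labels) and `confidence` (`NA` when absent).
#' @export
read_edge_list <- function(path,
                           dialect = c("trrust", "regnetwork", "dorothea",
                                       "generic3col"),
                           source = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(source)) source <- dialect
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  layout <- .edge_dialects[[dialect]]
  miss <- setdiff(unname(layout), names(tab))
  if (length(miss) > 0) {
    stop(sprintf("edge list '%s' (%s dialect) is missing mandatory column '%s'",
                 path, dialect, miss[1]), call. = FALSE)
  }
  n <- nrow(tab)
  if (n == 0) {
    return(data.frame(regulator = character(), target = character(),
                      mode = character(), sources = character(),
                      confidence = character(), stringsAsFactors = FALSE))
  }
  regulator <- trimws(tab[[layout[["regulator"]]]])
  target <- trimws(tab[[layout[["target"]]]])
  if (any(regulator == "") || any(target == "")) {
    i <- which(regulator == "" | target == "")[1]
    stop(sprintf("empty regulator or target symbol at data row %d", i),
         call. = FALSE)
  }
  if (dialect == "dorothea") {
    mor <- suppressWarnings(as.numeric(tab[[layout[["mor"]]]]))
    mode <- rep("unknown", n)
    mode[!is.na(mor) & mor > 0] <- "activation"
    mode[!is.na(mor) & mor < 0] <- "repression"
    confidence <- trimws(tab[[layout[["confidence"]]]])
    confidence[confidence == ""] <- NA_character_
  } else if (dialect == "regnetwork") {
    mode <- rep("unknown", n)
    confidence <- rep(NA_character_, n)
  } else {
    mode <- .normalize_mode(tab[[layout[["mode"]]]])
    confidence <- rep(NA_character_, n)
  }
  data.frame(regulator = regulator, target = target, mode = mode,
             sources = rep(source, n), confidence = confidence,
             stringsAsFactors = FALSE)
}

#' Write an edge table in the generic3col dialect
#'
#' Emits `regulator  target  mode` plus, when present, `sources` and
#' `confidence` columns (ignored by the generic3col reader).
#'
#' @param edges Edge data frame as returned by [read_edge_list()] or stored
#'   in a [regulatory_network].
#' @param path Output TSV.
#' @export
write_edge_list <- function(edges, path) {
  keep <- intersect(c("regulator", "target", "mode", "sources", "confidence"),
                    names(edges))
  utils::write.table(edges[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one term per line, tab-separated fields
#' `term_id  description  gene1  gene2 ...`. Duplicate genes within a term
#' are collapsed (set semantics).
#'
#' @param path GMT file.
#' @return Named list (one element per term, named by term id) of lists with
#'   elements `term_name` and `genes` (character vector, unique).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (length(f) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (f[1] %in% names(out)) {
      stop(sprintf("duplicate term id '%s' at GMT line %d", f[1], i),
           call. = FALSE)
    }
    out[[f[1]]] <- list(term_name = f[2], genes = genes)
  }
  out
}

#' Read a physical-interaction pair table
#'
#' STRING-style TSV with header `protein_a  protein_b  combined_score`.
#' Pairs are interpreted as unordered.
#'
#' @param path TSV file.
#' @return Data frame with columns `protein_a`, `protein_b`,
#'   `combined_score`.
#' @export
read_physical_pairs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "")
  req <- c("protein_a", "protein_b", "combined_score")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stop("physical pair table is missing column: ", miss[1], call. = FALSE)
  }
  tab$protein_a <- trimws(as.character(tab$protein_a))
  tab$protein_b <- trimws(as.character(tab$protein_b))
  tab$combined_score <- as.numeric(tab$combined_score)
  tab[, req, drop = FALSE]
}

#' Read a qPCR Ct table
#'
#' TSV with header `animal_id  group  gene  ct`; `group` must be `control`
#' or `case` and each (animal, gene) pair may appear once.
#'
#' @param path TSV file.
#' @return Data frame with those four columns.
#' @export
read_qpcr_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "")
  req <- c("animal_id", "group", "gene", "ct")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    stop("qPCR table is missing column: ", miss[1], call. = FALSE)
  }
  tab$animal_id <- trimws(as.character(tab$animal_id))
  tab$group <- trimws(as.character(tab$group))
  tab$gene <- trimws(as.character(tab$gene))
  tab$ct <- as.numeric(tab$ct)
  bad <- setdiff(unique(tab$group), c("control", "case"))
  if (length(bad) > 0) {
    stop("qPCR group must be 'control' or 'case', got: ", bad[1],
         call. = FALSE)
  }
  key <- paste(tab$animal_id, tab$gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate Ct record for animal '%s', gene '%s'",
                 d$animal_id, d$gene), call. = FALSE)
  }
  tab[, req, drop = FALSE]
}

#' Export a regulatory network to GraphML
#'
#' Writes a directed GraphML file (readable by Gephi, Cytoscape and igraph)
#' with per-edge `mode` and `sources` attributes and optional per-node
#' annotations such as `is_DE`, `direction` or `is_master_regulator`.
#'
#' @param net A [regulatory_network].
#' @param path Output file.
#' @param node_attrs Optional data frame of per-node annotations whose first
#'   column holds node ids; annotations for ids absent from the network are
#'   skipped with a warning.
#' @export
write_network_graphml <- function(net, path, node_attrs = NULL) {
  stopifnot(inherits(net, "regulatory_network"))
  g <- .rn_to_igraph(net)
  if (!is.null(node_attrs)) {
    node_attrs <- as.data.frame(node_attrs, stringsAsFactors = FALSE)
    ids <- as.character(node_attrs[[1]])
    unknown <- setdiff(ids, net$nodes$gene)
    if (length(unknown) > 0) {
      warning("skipping annotations for unknown node(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- ids %in% net$nodes$gene
    node_attrs <- node_attrs[keep, , drop = FALSE]
    idx <- match(as.character(node_attrs[[1]]), igraph::V(g)$name)
    for (cc in names(node_attrs)[-1]) {
      val <- node_attrs[[cc]]
      if (is.logical(val)) val <- tolower(as.character(val))
      full <- rep(NA_character_, igraph::vcount(g))
      full[idx] <- as.character(val)
      full[is.na(full)] <- ""
      g <- igraph::set_vertex_attr(g, cc, value = full)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(NULL)
}

# Internal: regulatory_network -> igraph (directed), preserving isolated
# nodes and the reference is_tf flag.
.rn_to_igraph <- function(net) {
  verts <- data.frame(name = net$nodes$gene,
                      is_tf = tolower(as.character(net$nodes$is_tf)),
                      stringsAsFactors = FALSE)
  ed <- net$edges
  el <- data.frame(from = ed$regulator, to = ed$target,
                   mode = ed$mode, sources = ed$sources,
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = TRUE, vertices = verts)
}
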