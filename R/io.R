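#' Write / read a taxon count table as TSV
#'
#' Counts go to `<stem>_counts.tsv` (taxa in rows, a `lineage` column of
#' semicolon-separated ranks, then one column per sample) and metadata to
#' `<stem>_metadata.tsv` (sample_id, timepoint, sex, ...). The round-trip is
#' lossless on canonicalized content.
#'
#' @param table a [taxa_count_table()].
#' @param stem file path stem (no extension).
#' @return (invisibly) the two file paths written.
#' @export
write_count_table <- function(table, stem) {
  stopifnot(inherits(table, "taxa_count_table"))
  cf <- paste0(stem, "_counts.tsv")
  mf <- paste0(stem, "_metadata.tsv")
  df <- data.frame(taxon = rownames(table$counts),
                   lineage = unname(table$lineage),
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- data.frame(sample_id = rownames(table$metadata), table$metadata,
                   stringsAsFactors = FALSE)
  utils::write.table(md, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = cf, metadata = mf))
}

#' @rdname write_count_table
#' @param timepoint_levels explicit ordering of timepoint labels (default:
#'   order of first appearance in the metadata file).
#' @export
read_count_table <- function(stem, timepoint_levels = NULL) {
  cf <- paste0(stem, "_counts.tsv")
  mf <- paste0(stem, "_metadata.tsv")
  df <- utils::read.delim(cf, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("taxon", "lineage") %in% names(df)))
    stop("read_count_table: missing taxon/lineage columns in ", cf)
  cnt <- as.matrix(df[, setdiff(names(df), c("taxon", "lineage")),
                      drop = FALSE])
  bad <- which(!is.finite(cnt), arr.ind = TRUE)
  if (nrow(bad))
    stop("read_count_table: non-numeric cell at data line ", bad[1, 1],
         " of ", cf)
  rownames(cnt) <- df$taxon
  if (all(cnt == round(cnt))) storage.mode(cnt) <- "integer"
  md <- utils::read.delim(mf, stringsAsFactors = FALSE)
  rownames(md) <- md$sample_id
  md$sample_id <- NULL
  lv <- if (is.null(timepoint_levels)) unique(md$timepoint)
  else timepoint_levels
  md$timepoint <- factor(md$timepoint, levels = lv, ordered = TRUE)
  taxa_count_table(cnt, df$lineage, md)
}

#' Write / read a gating dataset
#'
#' Proportions go to `<stem>_gating.csv` in long form (sample_id, node_path,
#' proportion_of_parent), the tree to `<stem>_tree.csv` (node, parent) and
#' metadata to `<stem>_metadata.csv`. Reading re-validates closure at every
#' sibling block and names the offending node and sample on failure.
#'
#' @param gating a [gating_dataset()].
#' @param stem file path stem.
#' @return (invisibly) the file paths written.
#' @export
write_gating_csv <- function(gating, stem) {
  stopifnot(inherits(gating, "gating_dataset"))
  gf <- paste0(stem, "_gating.csv")
  tf <- paste0(stem, "_tree.csv")
  mf <- paste0(stem, "_metadata.csv")
  P <- gating$proportions
  long <- data.frame(sample_id = rep(rownames(P), ncol(P)),
                     node_path = rep(node_paths(gating$tree), each = nrow(P)),
                     proportion_of_parent = as.vector(P),
                     stringsAsFactors = FALSE)
  utils::write.csv(long, gf, row.names = FALSE, quote = FALSE)
  utils::write.csv(gating$tree, tf, row.names = FALSE, quote = FALSE)
  md <- data.frame(sample_id = rownames(gating$metadata), gating$metadata,
                   stringsAsFactors = FALSE)
  utils::write.csv(md, mf, row.names = FALSE, quote = FALSE)
  invisible(c(gating = gf, tree = tf, metadata = mf))
}

node_paths <- function(tree) {
  vapply(tree$node, function(nd) {
    path <- nd
    cur <- nd
    repeat {
      par <- tree$parent[match(cur, tree$node)]
      if (is.na(par)) break
      path <- c(par, path)
      cur <- par
    }
    paste(path, collapse = "/")
  }, "")
}

#' @rdname write_gating_csv
#' @param timepoint_levels explicit timepoint ordering.
#' @export
read_gating_csv <- function(stem, timepoint_levels = NULL) {
  gf <- paste0(stem, "_gating.csv")
  tf <- paste0(stem, "_tree.csv")
  mf <- paste0(stem, "_metadata.csv")
  long <- utils::read.csv(gf, stringsAsFactors = FALSE)
  tree <- utils::read.csv(tf, stringsAsFactors = FALSE)
  tree$parent[tree$parent %in% c("", "NA")] <- NA_character_
  if (!is.numeric(long$proportion_of_parent)) {
    bad <- which(is.na(suppressWarnings(
      as.numeric(long$proportion_of_parent))))[1]
    stop("read_gating_csv: non-numeric proportion at data line ", bad,
         " of ", gf)
  }
  long$node <- vapply(strsplit(long$node_path, "/", fixed = TRUE),
                      function(p) p[length(p)], "")
  samples <- unique(long$sample_id)
  P <- matrix(NA_real_, length(samples), nrow(tree),
              dimnames = list(samples, tree$node))
  P[cbind(match(long$sample_id, samples), match(long$node, tree$node))] <-
    long$proportion_of_parent
  md <- utils::read.csv(mf, stringsAsFactors = FALSE)
  rownames(md) <- md$sample_id
  md$sample_id <- NULL
  lv <- if (is.null(timepoint_levels)) unique(md$timepoint)
  else timepoint_levels
  md$timepoint <- factor(md$timepoint, levels = lv, ordered = TRUE)
  gating_dataset(tree, P, md)
}

#' Write an association network to GraphML or GML
#'
#' @param graph an igraph object (e.g. from [build_network()]).
#' @param path output file path.
#' @param format "graphml" or "gml".
#' @return (invisibly) the path.
#' @export
write_network <- function(graph, path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  g <- graph
  class(g) <- "igraph"
  # GraphML writers reject NA attribute values
  for (at in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, at)
    if (is.character(v)) igraph::vertex_attr(g, at) <-
        ifelse(is.na(v), "", v)
  }
  for (at in igraph::edge_attr_names(g)) {
    v <- igraph::edge_attr(g, at)
    if (is.character(v)) igraph::edge_attr(g, at) <-
        ifelse(is.na(v), "", v)
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Pipeline configuration
#'
#' A single structured-text (YAML) configuration drives the full synthetic
#' workflow; every seed is explicit and the config round-trips through file
#' serialization losslessly.
#'
#' @param seed master seed.
#' @param out_dir output directory for stage files.
#' @param stages character vector of stages to run, in dependency order.
#' @param retain_prevalence,retain_abundance retain-resolve thresholds.
#' @param alpha_q,effect_min consensus-DA thresholds.
#' @param rho_cutoff,r_min,fdr_max network thresholds.
#' @param n_perm permutation count for PERMANOVA/Mantel/FDR stages.
#' @param n_null Erdos-Renyi replicates for topology validation.
#' @param sim extra arguments passed to [sim_config()].
#' @return list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1, out_dir = tempdir(),
                                    stages = c("simulate", "microbiome",
                                               "da", "cytometry",
                                               "integrate", "validate"),
                                    retain_prevalence = 0.10,
                                    retain_abundance = 1e-4,
                                    alpha_q = 0.01, effect_min = 1,
                                    rho_cutoff = 0.45, r_min = 0.6,
                                    fdr_max = 0.01,
                                    n_perm = 999, n_null = 1000,
                                    sim = list()) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
              retain_prevalence = retain_prevalence,
              retain_abundance = retain_abundance,
              alpha_q = alpha_q, effect_min = effect_min,
              rho_cutoff = rho_cutoff, r_min = r_min, fdr_max = fdr_max,
              n_perm = as.integer(n_perm), n_null = as.integer(n_null),
              sim = sim)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname default_pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname default_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- do.call(default_pipeline_config,
                 cfg[intersect(names(cfg),
                               names(formals(default_pipeline_config)))])
  cfg
}
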