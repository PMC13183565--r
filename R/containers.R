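#' Taxon count table with lineages and sample metadata
#'
#' The root object of the microbiome side of the pipeline: an integer taxon x
#' sample count matrix, a ranked taxonomy lineage per taxon, and per-sample
#' metadata (at least `timepoint`, an ordered factor, and `sex`).
#'
#' @param counts taxon x sample matrix of non-negative integers, with row and
#'   column names.
#' @param lineage character vector of semicolon-separated ranked lineages
#'   ("kingdom;phylum;...;species"), one per taxon.
#' @param metadata data frame with one row per sample; rownames are sample ids;
#'   must contain columns `timepoint` (ordered factor) and `sex`.
#' @return object of class `taxa_count_table`.
#' @export
taxa_count_table <- function(counts, lineage, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("taxa_count_table: counts need taxon rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("taxa_count_table: counts must be non-negative integers")
  if (length(lineage) != nrow(counts))
    stop("taxa_count_table: one lineage per taxon required")
  if (!all(colnames(counts) %in% rownames(metadata)))
    stop("taxa_count_table: every sample needs metadata")
  if (!all(c("timepoint", "sex") %in% colnames(metadata)))
    stop("taxa_count_table: metadata must contain timepoint and sex")
  metadata <- metadata[colnames(counts), , drop = FALSE]
  if (!is.ordered(metadata$timepoint))
    metadata$timepoint <- factor(metadata$timepoint,
                                 levels = unique(metadata$timepoint),
                                 ordered = TRUE)
  depth <- nlevels(factor(lengths(strsplit(lineage, ";", fixed = TRUE))))
  if (depth > 1L)
    stop("taxa_count_table: lineages have inconsistent rank depth")
  names(lineage) <- rownames(counts)
  structure(list(counts = counts, lineage = lineage, metadata = metadata),
            class = "taxa_count_table")
}

#' @export
print.taxa_count_table <- function(x, ...) {
  cat("taxa_count_table:", nrow(x$counts), "taxa x", ncol(x$counts),
      "samples\n")
  cat("timepoints:", paste(levels(x$metadata$timepoint), collapse = " < "),
      "\n")
  invisible(x)
}

#' @export
dim.taxa_count_table <- function(x) dim(x$counts)

#' Hierarchical gating dataset
#'
#' The root object of the cytometry side: a rooted gating tree plus, for each
#' sample and node, the node's proportion of its parent gate. Child proportions
#' of every internal node must sum to 1 and the root's proportion is 1.
#'
#' @param tree data frame with columns `node` and `parent` (`NA` for the root).
#' @param proportions sample x node matrix of fractions-of-parent in [0, 1];
#'   column names must match tree nodes.
#' @param metadata data frame, one row per sample (rownames = sample ids),
#'   with at least `timepoint` (ordered) and `sex`; `tissue` optional.
#' @param tol closure tolerance per sibling block.
#' @return object of class `gating_dataset`.
#' @export
gating_dataset <- function(tree, proportions, metadata, tol = 1e-9) {
  proportions <- as.matrix(proportions)
  stopifnot(is.data.frame(tree), all(c("node", "parent") %in% names(tree)))
  root <- tree$node[is.na(tree$parent)]
  if (length(root) != 1L) stop("gating_dataset: tree must have one root")
  if (!setequal(colnames(proportions), tree$node))
    stop("gating_dataset: proportion columns must match tree nodes")
  if (any(proportions < -tol | proportions > 1 + tol))
    stop("gating_dataset: proportions outside [0,1]")
  if (any(abs(proportions[, root] - 1) > tol))
    stop("gating_dataset: root proportion must be 1 for every sample")
  for (b in sibling_blocks(tree)) {
    s <- rowSums(proportions[, b, drop = FALSE])
    bad <- which(abs(s - 1) > tol)
    if (length(bad))
      stop("gating_dataset: children of '",
           tree$parent[match(b[1], tree$node)],
           "' do not sum to 1 for sample(s) ",
           paste(rownames(proportions)[bad], collapse = ", "))
  }
  metadata <- metadata[rownames(proportions), , drop = FALSE]
  if (!is.ordered(metadata$timepoint))
    metadata$timepoint <- factor(metadata$timepoint,
                                 levels = unique(metadata$timepoint),
                                 ordered = TRUE)
  structure(list(tree = tree, proportions = proportions, metadata = metadata),
            class = "gating_dataset")
}

#' @export
print.gating_dataset <- function(x, ...) {
  cat("gating_dataset:", nrow(x$proportions), "samples,",
      nrow(x$tree), "nodes,", length(sibling_blocks(x$tree)),
      "sibling blocks\n")
  invisible(x)
}

#' Sibling blocks of a gating tree
#'
#' Children of each internal node, in tree order. Each block is one
#' compositional unit: its fractions-of-parent sum to 1.
#'
#' @param tree gating tree data frame (`node`, `parent`).
#' @return list of character vectors of node names.
#' @export
sibling_blocks <- function(tree) {
  parents <- unique(tree$parent[!is.na(tree$parent)])
  lapply(parents, function(p) tree$node[!is.na(tree$parent) & tree$parent == p])
}

#' Leaf-level proportions of the total
#'
#' Multiplies fractions-of-parent down the tree to express each node as a
#' fraction of the root population.
#'
#' @param gating a [gating_dataset()].
#' @return sample x node matrix of fractions of the root.
#' @export
absolute_proportions <- function(gating) {
  tree <- gating$tree
  P <- gating$proportions
  out <- P
  for (i in seq_len(nrow(tree))) {
    path <- character()
    nd <- tree$node[i]
    cur <- nd
    repeat {
      par <- tree$parent[match(cur, tree$node)]
      if (is.na(par)) break
      path <- c(path, cur)
      cur <- par
    }
    out[, nd] <- if (length(path)) apply(P[, path, drop = FALSE], 1, prod) else 1
  }
  out
}
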