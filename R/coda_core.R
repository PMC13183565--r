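#' Close rows of a non-negative table to proportions
#'
#' Rescales each row of a sample x feature table so it sums to 1 (the closure
#' operation of compositional data analysis). Closure is idempotent and removes
#' any per-sample scale (sequencing depth, acquired event count).
#'
#' @param x numeric matrix or data frame, samples in rows, features in columns;
#'   entries must be non-negative.
#' @return numeric matrix with unit row sums; dimnames preserved.
#' @examples
#' closure(rbind(c(2, 2, 4), c(1, 0, 0)))
#' @export
closure <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("closure: negative entries are not a composition")
  rs <- rowSums(x)
  bad <- which(rs <= 0)
  if (length(bad)) {
    nm <- rownames(x)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("closure: degenerate all-zero sample(s): ", paste(nm, collapse = ", "))
  }
  sweep(x, 1, rs, "/")
}

#' Multiplicative zero replacement
#'
#' Replaces zeros of a closed composition by a small value `delta` and rescales
#' the non-zero parts of each row by (1 - z * delta), where z is the number of
#' zeros in that row, so closure is conserved exactly.
#'
#' @param comp closed composition matrix (rows sum to 1).
#' @param delta replacement value; a scalar must be smaller than the smallest
#'   positive entry of every row. Default (`NULL`): per-row, half the row's
#'   smallest positive entry — an adaptive, scale-free choice that keeps the
#'   imputed value tied to each sample's own detection floor rather than
#'   collapsing absent features to one shared constant.
#' @return composition matrix with strictly positive entries, rows summing to 1.
#' @examples
#' replace_zeros(rbind(c(0, 0.4, 0.6)), delta = 0.01)
#' @export
replace_zeros <- function(comp, delta = NULL) {
  comp <- as.matrix(comp)
  if (any(comp < 0)) stop("replace_zeros: negative entries")
  if (!any(comp == 0)) return(comp)
  minpos_row <- apply(comp, 1, function(r)
    if (any(r > 0)) min(r[r > 0]) else NA_real_)
  if (any(is.na(minpos_row))) stop("replace_zeros: all-zero row")
  if (is.null(delta)) {
    drow <- 0.5 * minpos_row
  } else {
    if (length(delta) != 1L || delta <= 0)
      stop("replace_zeros: delta must be a positive scalar")
    if (delta >= min(minpos_row))
      stop("replace_zeros: delta (", format(delta),
           ") is not below the smallest positive entry (",
           format(min(minpos_row)), ")")
    drow <- rep(delta, nrow(comp))
  }
  z <- rowSums(comp == 0)
  if (any(z * drow >= 1))
    stop("replace_zeros: delta too large for a row with ", max(z), " zeros")
  out <- sweep(comp, 1, 1 - z * drow, "*")
  idx <- which(comp == 0, arr.ind = TRUE)
  out[idx] <- drow[idx[, 1]]
  out
}

#' Centered log-ratio (CLR) transform
#'
#' Maps each row x of a strictly positive composition to
#' log(x_i / g(x)) with g the row geometric mean. CLR rows sum to zero and the
#' transform is invariant to per-sample scaling, which makes it the workhorse
#' representation for relative-abundance data.
#'
#' @param comp matrix of strictly positive values (zeros must be replaced
#'   first, see [replace_zeros()]); rows need not be closed.
#' @return matrix of the same dimension; each row sums to 0.
#' @examples
#' clr(rbind(c(0.5, 0.25, 0.25)))
#' @export
clr <- function(comp) {
  comp <- as.matrix(comp)
  if (any(comp <= 0))
    stop("clr: non-positive entries; unzero first with replace_zeros()")
  lx <- log(comp)
  sweep(lx, 1, rowMeans(lx), "-")
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between the CLR transforms of two strictly positive
#' composition vectors. A proper metric on the simplex, invariant under
#' perturbation (componentwise multiplication followed by closure).
#'
#' @param x,y strictly positive numeric vectors over the same features.
#' @return non-negative scalar.
#' @examples
#' aitchison_distance(c(0.5, 0.25, 0.25), c(1, 1, 1) / 3)
#' @export
aitchison_distance <- function(x, y) {
  if (length(x) != length(y))
    stop("aitchison_distance: feature dimension mismatch")
  cx <- drop(clr(rbind(x)))
  cy <- drop(clr(rbind(y)))
  sqrt(sum((cx - cy)^2))
}

#' All-pairs Aitchison distance matrix
#'
#' @param comp strictly positive sample x feature matrix.
#' @return a `dist`-convertible symmetric matrix of sample distances.
#' @keywords internal
aitchison_dist_matrix <- function(comp) {
  as.matrix(stats::dist(clr(comp)))
}

#' Unzeroing, stabilization and standardization (USS) of gating data
#'
#' Normalizes hierarchical flow-cytometry proportions for cross-dataset
#' analysis in three steps: (1) unzero each sibling block of the gating tree
#' by multiplicative replacement, (2) stabilize by a CLR transform within each
#' sibling block (the compositional unit of the gating hierarchy), and
#' (3) standardize each retained column to mean 0, sd 1 across samples.
#' For two-child blocks the two CLR columns are exact negatives of one another,
#' so the second (complement) column is dropped as redundant; further columns
#' can be dropped by name via `drop`.
#'
#' @param gating a [gating_dataset()].
#' @param delta zero-replacement value per block; default half the smallest
#'   positive proportion of the block.
#' @param drop character vector of node names to exclude (e.g. double-negative
#'   quadrants measured under the same parent).
#' @return sample x population matrix of standardized log-ratio scores.
#' @export
uss_transform <- function(gating, delta = NULL, drop = NULL) {
  stopifnot(inherits(gating, "gating_dataset"))
  blocks <- sibling_blocks(gating$tree)
  cols <- list()
  for (b in blocks) {
    P <- closure(gating$proportions[, b, drop = FALSE])
    P <- replace_zeros(P, delta = delta)
    Z <- clr(P)
    keep <- if (length(b) == 2L) b[1L] else b
    cols[[length(cols) + 1L]] <- Z[, keep, drop = FALSE]
  }
  out <- do.call(cbind, cols)
  if (!is.null(drop)) out <- out[, setdiff(colnames(out), drop), drop = FALSE]
  sds <- apply(out, 2, stats::sd)
  const <- sds < 1e-12
  if (any(const)) {
    warning("uss_transform: dropping constant column(s): ",
            paste(colnames(out)[const], collapse = ", "))
    out <- out[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  scale(out)[, , drop = FALSE]
}
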