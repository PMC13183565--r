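#' Mantel test between two distance matrices
#'
#' Pearson correlation of the n(n-1)/2 off-diagonal entries, with a one-sided
#' (greater) permutation p-value obtained by jointly permuting the rows and
#' columns of the second matrix. When `strata` is given, permutations are
#' restricted within strata (e.g. within sex), giving the stratified variant
#' used as a covariate-adjusted Mantel test.
#'
#' @param D1,D2 symmetric distance matrices over the same samples, same
#'   order.
#' @param n_perm number of permutations (default 999).
#' @param strata optional vector of stratum labels per sample.
#' @param seed integer seed for the permutation stream.
#' @return object of class `mantel_result`: `r`, `p`, `n_perm`, `strata`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, strata = NULL, seed = 1) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  n <- nrow(D1)
  if (n < 4) stop("mantel_test: need at least 4 samples")
  if (!all(dim(D1) == dim(D2)))
    stop("mantel_test: matrices differ in size")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    stop("mantel_test: sample sets/order differ")
  lower <- lower.tri(D1)
  v1 <- D1[lower]
  r_obs <- stats::cor(v1, D2[lower])
  set.seed(seed)
  perms <- strata_permutations(n, n_perm, strata)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    pm <- perms[i, ]
    stats::cor(v1, D2[pm, pm][lower])
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  structure(list(r = r_obs, p = p, n_perm = n_perm,
                 strata = if (is.null(strata)) NULL else as.character(strata),
                 r_perm = r_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations%s)\n",
              x$r, x$p, x$n_perm,
              if (is.null(x$strata)) "" else ", stratified"))
  invisible(x)
}

# n_perm x n matrix of sample permutations, restricted within strata
strata_permutations <- function(n, n_perm, strata = NULL) {
  out <- matrix(0L, n_perm, n)
  if (is.null(strata)) {
    for (i in seq_len(n_perm)) out[i, ] <- sample.int(n)
  } else {
    strata <- as.factor(strata)
    idx <- split(seq_len(n), strata)
    for (i in seq_len(n_perm)) {
      pm <- seq_len(n)
      for (s in idx) pm[s] <- s[sample.int(length(s))]
      out[i, ] <- pm
    }
  }
  out
}

#' Proportionality (rho) between CLR-transformed features
#'
#' The log-ratio-variance association measure
#' rho(i, j) = 1 - var(clr_i - clr_j) / (var(clr_i) + var(clr_j)) =
#' 2 cov(clr_i, clr_j) / (var(clr_i) + var(clr_j)), a compositionally valid
#' alternative to correlation: it is 1 exactly for identical CLR columns,
#' -1 in the anti-proportional limit, and robust to closure-induced spurious
#' correlation. Each dataset should be CLR-transformed separately before
#' column-concatenation.
#'
#' @param clr_mat sample x feature matrix of CLR (or otherwise log-ratio)
#'   values; at least 3 samples.
#' @return symmetric feature x feature matrix of rho, unit diagonal;
#'   zero-variance features give NA rows/columns.
#' @export
proportionality_rho <- function(clr_mat) {
  m <- as.matrix(clr_mat)
  if (nrow(m) < 3) stop("proportionality_rho: need >= 3 samples")
  V <- stats::cov(m)
  v <- diag(V)
  denom <- outer(v, v, "+")
  rho <- 2 * V / denom
  bad <- v < 1e-300
  if (any(bad)) {
    rho[bad, ] <- NA_real_
    rho[, bad] <- NA_real_
  }
  diag(rho) <- ifelse(bad, NA_real_, 1)
  dimnames(rho) <- list(colnames(m), colnames(m))
  rho
}

#' Permutation FDR curve over association cutoffs
#'
#' For each permutation, every feature column is row-shuffled independently
#' (breaking all cross-feature association while preserving marginals), the
#' association matrix is recomputed, and the estimated FDR at cutoff c is
#' the mean permuted count of |association| > c divided by the observed
#' count. This is the cutoff-selection device used to pick association
#' thresholds with a stated FDR.
#'
#' @param data sample x feature matrix the association is computed from
#'   (CLR values for rho, any values for Spearman).
#' @param cutoffs grid of cutoffs to evaluate.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param method "rho" or "spearman".
#' @return object of class `fdr_curve`: data frame `curve` (cutoff,
#'   n_observed, mean_permuted, fdr [clipped to 0..1 and monotonized so the
#'   curve is non-increasing in the cutoff], the raw ratio `fdr_raw`, and a
#'   zero_observed flag), plus `n_perm` and `method`.
#' @export
update_cutoffs <- function(data, cutoffs = seq(0.05, 0.95, by = 0.05),
                           n_perm = 100, seed = 1,
                           method = c("rho", "spearman")) {
  method <- match.arg(method)
  if (n_perm < 100) stop("update_cutoffs: n_perm must be >= 100")
  m <- as.matrix(data)
  assoc <- function(x) {
    a <- switch(method,
                rho = proportionality_rho(x),
                spearman = stats::cor(x, method = "spearman"))
    abs(a[upper.tri(a)])
  }
  obs <- assoc(m)
  n_obs <- vapply(cutoffs, function(c) sum(obs > c, na.rm = TRUE), 0)
  set.seed(seed)
  perm_counts <- matrix(0, n_perm, length(cutoffs))
  n <- nrow(m)
  for (i in seq_len(n_perm)) {
    mp <- apply(m, 2, function(col) col[sample.int(n)])
    pv <- assoc(mp)
    perm_counts[i, ] <- vapply(cutoffs, function(c)
      sum(pv > c, na.rm = TRUE), 0)
  }
  mean_perm <- colMeans(perm_counts)
  fdr_raw <- ifelse(n_obs > 0, pmin(mean_perm / n_obs, 1), 0)
  # monotonize: the reported FDR at a cutoff is the best (smallest) estimate
  # achievable at or below it, so the curve is non-increasing in the cutoff
  fdr <- cummin(fdr_raw)
  curve <- data.frame(cutoff = cutoffs, n_observed = n_obs,
                      mean_permuted = mean_perm, fdr = fdr,
                      fdr_raw = fdr_raw,
                      zero_observed = n_obs == 0)
  structure(list(curve = curve, n_perm = n_perm, method = method),
            class = "fdr_curve")
}

#' @export
print.fdr_curve <- function(x, ...) {
  cat("permutation FDR curve (", x$method, ", ", x$n_perm, " perms):\n",
      sep = "")
  print(x$curve, row.names = FALSE, digits = 3)
  invisible(x)
}

# Spearman p-value by the t approximation
spearman_p <- function(r, n) {
  t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Spearman association network on separately CLR-transformed datasets
#'
#' Computes Spearman correlations for all within- and cross-dataset feature
#' pairs of the column-concatenated CLR matrices, with p-values from the t
#' approximation and BH correction across all pairs. Edges require |r| >
#' `r_min` and q < `fdr_max`; an optional leave-one-out influence screen
#' drops edges whose |r| falls below `r_min` when any single sample is
#' removed (an automated replacement for manual scatter-plot screening of
#' outlier-driven hits). Bootstrap support (fraction of sample resamples in
#' which |r| > `r_min`) is recorded per edge.
#'
#' @param clr_micro,clr_immune sample x feature CLR matrices sharing samples
#'   (rows aligned).
#' @param r_min minimum |Spearman r| (default 0.6).
#' @param fdr_max maximum BH q (default 0.01).
#' @param n_boot bootstrap replicates for edge support (default 500; 0
#'   disables).
#' @param seed integer seed for the bootstrap.
#' @param loo_screen apply the leave-one-out influence screen (default TRUE).
#' @return data frame of edges: source, target, r, p, q, sign,
#'   bootstrap_support, cross (TRUE for microbe-immune edges).
#' @export
spearman_clr_network <- function(clr_micro, clr_immune, r_min = 0.6,
                                 fdr_max = 0.01, n_boot = 500, seed = 1,
                                 loo_screen = TRUE) {
  A <- as.matrix(clr_micro); B <- as.matrix(clr_immune)
  if (nrow(A) != nrow(B))
    stop("spearman_clr_network: datasets must share samples")
  M <- cbind(A, B)
  ties <- vapply(seq_len(ncol(M)), function(j) {
    tb <- table(M[, j]); max(tb) / nrow(M)
  }, numeric(1))
  if (any(ties > 0.5))
    warning("spearman_clr_network: rank degeneracy (>50% ties) in feature(s): ",
            paste(colnames(M)[ties > 0.5], collapse = ", "))
  n <- nrow(M)
  R <- stats::cor(M, method = "spearman")
  ut <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[upper.tri(R)]
  p <- spearman_p(r, n)
  q <- bh_adjust(p)
  keep <- abs(r) > r_min & q < fdr_max
  edges <- data.frame(source = colnames(M)[ut[keep, 1]],
                      target = colnames(M)[ut[keep, 2]],
                      r = r[keep], p = p[keep], q = q[keep],
                      stringsAsFactors = FALSE)
  if (nrow(edges) && loo_screen) {
    ok <- vapply(seq_len(nrow(edges)), function(i) {
      x <- M[, edges$source[i]]; y <- M[, edges$target[i]]
      all(vapply(seq_len(n), function(s)
        abs(stats::cor(x[-s], y[-s], method = "spearman")), 0) > r_min)
    }, logical(1))
    edges <- edges[ok, , drop = FALSE]
  }
  edges$sign <- ifelse(edges$r > 0, 1L, -1L)
  edges$bootstrap_support <- NA_real_
  if (nrow(edges) && n_boot > 0) {
    set.seed(seed)
    hits <- matrix(FALSE, n_boot, nrow(edges))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      for (i in seq_len(nrow(edges))) {
        rb <- stats::cor(M[idx, edges$source[i]], M[idx, edges$target[i]],
                         method = "spearman")
        hits[b, i] <- is.finite(rb) && abs(rb) > r_min
      }
    }
    edges$bootstrap_support <- colMeans(hits)
  }
  edges$cross <- (edges$source %in% colnames(A)) !=
    (edges$target %in% colnames(A))
  rownames(edges) <- NULL
  edges
}

#' Assemble a typed microbe-immune association network
#'
#' Builds a simple undirected igraph from an edge list, typing each node as
#' a taxon or an immune cell (with tissue of origin for cells). Nodes can be
#' restricted to a declared universe (e.g. the consensus-DA taxon set and a
#' curated immune-cell feature list) so that isolated declared features
#' remain present as unconnected nodes.
#'
#' @param edges data frame with columns `source`, `target`, `weight` (or
#'   `r`/`rho`), and optionally `sign`, `method`.
#' @param taxa character vector of taxon node ids.
#' @param cells character vector of immune-cell node ids.
#' @param cell_tissue optional named vector mapping cell ids to tissues.
#' @return igraph object with vertex attributes `type` and `tissue` and
#'   edge attributes `weight`, `sign`, `method`; class
#'   `c("assoc_network", "igraph")`.
#' @export
build_network <- function(edges, taxa, cells, cell_tissue = NULL) {
  nodes <- data.frame(name = c(taxa, cells),
                      type = c(rep("taxon", length(taxa)),
                               rep("immune_cell", length(cells))),
                      stringsAsFactors = FALSE)
  nodes$tissue <- NA_character_
  if (!is.null(cell_tissue))
    nodes$tissue[match(names(cell_tissue), nodes$name)] <-
      unname(cell_tissue)
  if (nrow(edges)) {
    wcol <- intersect(c("weight", "r", "rho"), names(edges))[1]
    if (is.na(wcol)) stop("build_network: no weight column")
    unknown <- setdiff(c(edges$source, edges$target), nodes$name)
    if (length(unknown))
      stop("build_network: edges reference unknown features: ",
           paste(unknown, collapse = ", "))
    el <- data.frame(from = edges$source, to = edges$target,
                     weight = edges[[wcol]],
                     sign = if ("sign" %in% names(edges)) edges$sign
                     else ifelse(edges[[wcol]] > 0, 1L, -1L),
                     method = if ("method" %in% names(edges))
                       edges$method else NA_character_,
                     stringsAsFactors = FALSE)
    key <- apply(cbind(pmin(el$from, el$to), pmax(el$from, el$to)), 1,
                 paste, collapse = "\r")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)]
      w_by_key <- split(el$weight, key)
      conflicting <- any(vapply(w_by_key, function(w)
        max(w) - min(w) > 1e-12, logical(1)))
      if (conflicting)
        stop("build_network: duplicate edge(s) with conflicting weights")
      el <- el[!duplicated(key), , drop = FALSE]
    }
    if (any(el$from == el$to))
      stop("build_network: self-loops are not allowed")
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                       vertices = nodes)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = character(), to = character()),
      directed = FALSE, vertices = nodes)
  }
  class(g) <- c("assoc_network", class(g))
  g
}
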