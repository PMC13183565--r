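#' Uniform Erdos-Renyi G(n, m) random graph
#'
#' Draws a simple undirected graph uniformly from the set of labeled graphs
#' with exactly `n` nodes and `m` edges, by sampling `m` distinct vertex
#' pairs without replacement from all n(n-1)/2 pairs. This is the null model
#' matched on node and edge count used to validate observed network
#' topology.
#'
#' @param n number of nodes.
#' @param m number of edges (0 <= m <= n(n-1)/2).
#' @param seed optional integer seed (omit to use the current RNG stream,
#'   e.g. inside a seeded replicate loop).
#' @return igraph object with `n` vertices and `m` edges.
#' @export
er_random_graph <- function(n, m, seed = NULL) {
  max_m <- n * (n - 1) / 2
  if (m < 0 || m > max_m)
    stop("er_random_graph: m must be in [0, ", max_m, "]")
  if (!is.null(seed)) set.seed(seed)
  pair_idx <- sample.int(max_m, m)
  # decode linear index of the upper triangle (column-major) to (i, j)
  j <- ceiling((1 + sqrt(1 + 8 * pair_idx)) / 2)
  i <- pair_idx - (j - 1) * (j - 2) / 2
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (m > 0) g <- igraph::add_edges(g, as.vector(rbind(i, j)))
  g
}

#' Topology summary of a simple graph
#'
#' Computes the standard metrics used to compare an observed association
#' network against its random-graph null: density (2m / n(n-1)), average
#' degree (AD = 2m/n), average local clustering coefficient (ACC; nodes of
#' degree < 2 contribute 0), average shortest-path length (APL; unweighted
#' BFS, averaged over connected ordered pairs), diameter (largest finite
#' shortest path), mean betweenness (unnormalized, each unordered pair
#' counted once), modularity of a Louvain partition at resolution 1 (fixed
#' seed, as the algorithm is stochastic), and the number of connected
#' components.
#'
#' @param graph an igraph object (simple, undirected).
#' @param modularity_seed seed for the Louvain pass.
#' @return object of class `topology_summary` (named list of metrics).
#' @export
topology_summary <- function(graph, modularity_seed = 1) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::any_multiple(graph) || any(igraph::which_loop(graph)))
    stop("topology_summary: graph must be simple")
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  if (n == 0) {
    out <- list(n_nodes = 0, n_edges = 0, density = 0, average_degree = 0,
                acc = 0, apl = NA_real_, diameter = NA_real_,
                modularity = 0, mean_betweenness = 0, component_count = 0)
    class(out) <- "topology_summary"
    return(out)
  }
  density <- if (n > 1) 2 * m / (n * (n - 1)) else 0
  ad <- 2 * m / n
  acc <- if (m > 0)
    mean(igraph::transitivity(graph, type = "local", isolates = "zero"))
  else 0
  apl <- if (m > 0) igraph::mean_distance(graph, weights = NA, unconnected = TRUE)
  else NA_real_
  diam <- if (m > 0) igraph::diameter(graph, weights = NA, unconnected = TRUE)
  else NA_real_
  btw <- mean(igraph::betweenness(graph, directed = FALSE, weights = NA,
                                  normalized = FALSE))
  mod <- if (m > 0) {
    # fix the Louvain seed without disturbing the caller's RNG stream
    # (topology_summary runs inside seeded replicate loops)
    old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    set.seed(modularity_seed)
    val <- igraph::modularity(igraph::cluster_louvain(
      graph, weights = NA, resolution = 1))
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = .GlobalEnv)
    val
  } else 0
  out <- list(n_nodes = n, n_edges = m, density = density,
              average_degree = ad, acc = acc, apl = apl, diameter = diam,
              modularity = mod, mean_betweenness = btw,
              component_count = igraph::components(graph)$no)
  class(out) <- "topology_summary"
  out
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0("graph: %d nodes, %d edges | density %.3f, AD %.2f, ",
                     "ACC %.3f, APL %.3f, diameter %s, modularity %.3f, ",
                     "mean betweenness %.2f, %d component(s)\n"),
              x$n_nodes, x$n_edges, x$density, x$average_degree, x$acc,
              x$apl, format(x$diameter), x$modularity, x$mean_betweenness,
              x$component_count))
  invisible(x)
}

#' Z-test comparison against the Erdos-Renyi null
#'
#' Generates `B` G(n, m) replicates matched on the observed graph's node and
#' edge count, summarizes each, and reports per metric the null mean and sd,
#' the Z-score of the observed value, and a two-sided normal p-value.
#'
#' @param graph observed igraph object.
#' @param B number of null replicates (>= 100; default 1000).
#' @param seed integer seed for the replicate stream.
#' @param metrics which metrics to compare.
#' @return object of class `null_comparison`: data frame `comparison`
#'   (metric, observed, null_mean, null_sd, Z, p), `B`, `seed`.
#' @export
null_compare <- function(graph, B = 1000, seed = 1,
                         metrics = c("density", "average_degree", "acc",
                                     "apl", "diameter", "modularity",
                                     "mean_betweenness")) {
  if (B < 100) stop("null_compare: B must be >= 100")
  obs <- topology_summary(graph)
  n <- obs$n_nodes; m <- obs$n_edges
  set.seed(seed)
  draws <- matrix(NA_real_, B, length(metrics),
                  dimnames = list(NULL, metrics))
  for (b in seq_len(B)) {
    ts <- topology_summary(er_random_graph(n, m))
    draws[b, ] <- unlist(ts[metrics])
  }
  null_mean <- colMeans(draws, na.rm = TRUE)
  null_sd <- apply(draws, 2, stats::sd, na.rm = TRUE)
  observed <- unlist(obs[metrics])
  Z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  cmp <- data.frame(metric = metrics, observed = observed,
                    null_mean = null_mean, null_sd = null_sd, Z = Z,
                    p = 2 * stats::pnorm(-abs(Z)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(comparison = cmp, B = B, seed = seed),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat("Erdos-Renyi null comparison (B =", x$B, "):\n")
  print(x$comparison, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Correlation-to-distance conversion
#'
#' Converts an association r in [-1, 1] to a dissimilarity. The default is
#' d = sqrt(2 (1 - r)), the chord distance between unit-variance variables
#' (identical variables map to 0, anti-correlated ones to 2); `squared =
#' TRUE` gives the plain 2 (1 - r) form.
#'
#' @param r numeric vector/matrix of associations in [-1, 1].
#' @param squared use 2(1 - r) instead of its square root.
#' @return dissimilarities, same shape as `r`.
#' @export
cor_to_dist <- function(r, squared = FALSE) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("cor_to_dist: |r| > 1")
  r <- pmin(pmax(r, -1), 1)
  if (squared) 2 * (1 - r) else sqrt(2 * (1 - r))
}

#' Ward clustering with by-cluster-correlation model selection
#'
#' Ward-linkage hierarchical clustering of features on cor_to_dist
#' dissimilarities, with the number of clusters chosen by the by-cluster
#' correlation criterion: for each k, every entry of the association matrix
#' is replaced by the mean association of its cluster-pair block, the
#' off-diagonal entries of this block-averaged matrix are correlated with
#' the observed ones, and the smallest k whose correlation reaches
#' `min_cor` is selected (k_max with a flag if none does).
#'
#' @param assoc square symmetric association matrix (e.g. rho or Spearman).
#' @param min_cor by-cluster correlation threshold (default 0.85).
#' @param k_max largest k to consider (default: number of features).
#' @return list of class `ward_cluster_fit`: `dendrogram` (hclust), `k`,
#'   `labels` (named cluster ids), `criterion` (by-cluster correlation per
#'   k), `reached` (logical flag).
#' @export
ward_cluster_select <- function(assoc, min_cor = 0.85, k_max = NULL) {
  A <- as.matrix(assoc)
  if (nrow(A) != ncol(A) || max(abs(A - t(A)), na.rm = TRUE) > 1e-8)
    stop("ward_cluster_select: association matrix must be square symmetric")
  p <- nrow(A)
  if (is.null(k_max)) k_max <- p
  k_max <- min(k_max, p)
  d <- stats::as.dist(cor_to_dist(A))
  hc <- stats::hclust(d, method = "ward.D2")
  off <- upper.tri(A)
  obs_vec <- A[off]
  crit <- numeric(k_max)
  labels_by_k <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    cl <- stats::cutree(hc, k = k)
    labels_by_k[[k]] <- cl
    By <- by_cluster_matrix(A, cl)
    bv <- By[off]
    if (stats::sd(bv) < 1e-12 || stats::sd(obs_vec) < 1e-12) {
      crit[k] <- if (max(abs(bv - obs_vec)) < 1e-9) 1 else 0
    } else {
      crit[k] <- stats::cor(obs_vec, bv)
    }
  }
  hit <- which(crit >= min_cor)
  reached <- length(hit) > 0
  k_sel <- if (reached) min(hit) else k_max
  structure(list(dendrogram = hc, k = k_sel,
                 labels = labels_by_k[[k_sel]],
                 criterion = stats::setNames(crit, seq_len(k_max)),
                 reached = reached, min_cor = min_cor),
            class = "ward_cluster_fit")
}

#' By-cluster (block-averaged) association matrix
#'
#' Replaces each entry of an association matrix by the mean association of
#' its cluster-pair block (off-diagonal entries only for same-cluster
#' blocks; singleton same-cluster blocks keep the diagonal value).
#'
#' @param A square association matrix.
#' @param labels integer cluster labels per feature.
#' @return matrix of the same dimension.
#' @export
by_cluster_matrix <- function(A, labels) {
  p <- nrow(A)
  out <- A
  for (a in unique(labels)) {
    for (b in unique(labels)) {
      ia <- which(labels == a); ib <- which(labels == b)
      blk <- A[ia, ib, drop = FALSE]
      if (a == b) {
        if (length(ia) == 1L) next
        mval <- mean(blk[upper.tri(blk) | lower.tri(blk)])
        sub <- out[ia, ib, drop = FALSE]
        sub[upper.tri(sub) | lower.tri(sub)] <- mval
        out[ia, ib] <- sub
      } else {
        out[ia, ib] <- mean(blk)
      }
    }
  }
  out
}
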