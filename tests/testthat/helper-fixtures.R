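# shared fixtures, built in code

toy_counts <- function() {
  # 5 taxa x 4 samples; A, B abundant everywhere; C, D rare strains of one
  # genus; E a singleton spurious sequence
  counts <- rbind(
    A = c(500, 400, 450, 420),
    B = c(300, 350, 320, 310),
    C = c(4, 6, 0, 5),
    D = c(6, 0, 8, 5),
    E = c(1, 0, 0, 0)
  )
  colnames(counts) <- paste0("s", 1:4)
  lineage <- c(
    "Bacteria;p1;c1;o1;f1;gA;A",
    "Bacteria;p1;c1;o1;f1;gB;B",
    "Bacteria;p1;c1;o1;f2;gCD;C",
    "Bacteria;p1;c1;o1;f2;gCD;D",
    "Bacteria;p1;c1;o1;f3;gE;E"
  )
  md <- data.frame(
    timepoint = factor(c("t1", "t1", "t2", "t2"),
                       levels = c("t1", "t2"), ordered = TRUE),
    sex = c("F", "M", "F", "M"),
    row.names = paste0("s", 1:4)
  )
  taxa_count_table(counts, lineage, md)
}

toy_gating <- function(n = 12, seed = 1) {
  cfg <- sim_config(seed = seed, n_per_group = max(2, ceiling(n / 8)))
  simulate_cytometry(cfg)
}

# brute-force graph metrics for the oracle comparisons (plain BFS and
# triangle counting; independent of igraph)
brute_metrics <- function(adj) {
  n <- nrow(adj)
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  # local clustering by triangle counting
  acc_i <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
  # BFS all-pairs shortest paths
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (u in frontier) {
        nb <- which(adj[u, ] == 1)
        new <- nb[d[nb] == Inf]
        d[new] <- d[u] + 1
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
  }
  finite <- dist[is.finite(dist) & dist > 0]
  list(
    density = if (n > 1) 2 * m / (n * (n - 1)) else 0,
    average_degree = if (n > 0) 2 * m / n else 0,
    acc = if (n > 0) mean(acc_i) else 0,
    apl = if (length(finite)) mean(finite) else NA_real_,
    diameter = if (length(finite)) max(finite) else NA_real_
  )
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
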