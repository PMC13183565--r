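test_that("Mantel self-comparison and oracle agreement", {
  set.seed(31)
  X <- matrix(rnorm(30), 10, 3)
  D <- as.matrix(dist(X))
  res <- mantel_test(D, D, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 200)
  # statistic agrees with the vegan implementation (independent oracle)
  Y <- matrix(rnorm(30), 10, 3)
  D2 <- as.matrix(dist(Y))
  ours <- mantel_test(D, D2, n_perm = 99, seed = 1)
  veg <- vegan::mantel(as.dist(D), as.dist(D2), permutations = 99)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)
  expect_error(mantel_test(D, D2[1:9, 1:9]), "size")
})

test_that("stratified permutations never cross strata", {
  strata <- rep(c("F", "M"), each = 6)
  set.seed(2)
  perms <- codamia:::strata_permutations(12, 200, strata)
  for (i in seq_len(nrow(perms))) {
    expect_identical(strata[perms[i, ]], strata)
  }
  # and actually permute within strata
  expect_gt(mean(perms != matrix(1:12, 200, 12, byrow = TRUE)), 0.5)
})

test_that("proportionality rho matches its defining formula", {
  set.seed(33)
  M <- matrix(rnorm(30), 5, 6)
  colnames(M) <- paste0("f", 1:6)
  rho <- proportionality_rho(M)
  for (i in 1:5) for (j in (i + 1):6) {
    direct <- 1 - var(M[, i] - M[, j]) / (var(M[, i]) + var(M[, j]))
    expect_equal(rho[i, j], direct, tolerance = 1e-12)
  }
  expect_equal(diag(rho), rep(1, 6), ignore_attr = TRUE)
  expect_equal(rho, t(rho))
  # exact limits
  M2 <- cbind(a = M[, 1], b = M[, 1], c = -M[, 1])
  rho2 <- proportionality_rho(M2)
  expect_equal(rho2["a", "b"], 1)
  expect_equal(rho2["a", "c"], -1)
  # zero-variance feature reported missing
  M3 <- cbind(M, const = 1)
  expect_true(all(is.na(proportionality_rho(M3)[, "const"])))
})

test_that("permutation FDR curve behaves on noise and on signal", {
  set.seed(34)
  noise <- matrix(rnorm(40 * 12), 40)
  fc <- update_cutoffs(noise, cutoffs = c(0.05, 0.3, 0.6), n_perm = 100,
                       seed = 1, method = "rho")
  expect_gte(fc$curve$fdr[1], 0.8)  # near-zero cutoffs call everything
  expect_true(all(fc$curve$fdr >= 0 & fc$curve$fdr <= 1))
  # planted proportional pairs push FDR below 0.05 at a moderate cutoff
  z <- matrix(rnorm(40 * 4), 40)
  signal <- cbind(z + matrix(rnorm(160, 0, 0.3), 40),
                  z + matrix(rnorm(160, 0, 0.3), 40),
                  matrix(rnorm(40 * 6), 40))
  fs <- update_cutoffs(signal, cutoffs = seq(0.1, 0.6, 0.1), n_perm = 100,
                       seed = 2, method = "rho")
  expect_true(any(fs$curve$fdr < 0.05 & fs$curve$cutoff <= 0.6))
  expect_error(update_cutoffs(noise, n_perm = 50), ">= 100")
})

test_that("FDR curves are non-increasing in the cutoff (after clipping)", {
  set.seed(35)
  for (s in 1:5) {
    M <- matrix(rnorm(30 * 10), 30) +
      matrix(rnorm(30), 30, 10) * 0.5  # shared factor
    fc <- update_cutoffs(M, cutoffs = seq(0.1, 0.9, 0.1), n_perm = 100,
                         seed = s)
    keep <- !fc$curve$zero_observed
    expect_true(all(diff(fc$curve$fdr[keep]) <= 1e-12))
  }
})

test_that("Spearman edges match hand-computed ranks and rank invariance", {
  A <- cbind(t1 = c(3, 1, 4, 1.5, 5), t2 = c(2.2, 0.4, 1.9, 3.3, 0.1))
  B <- cbind(c1 = c(10, 2, 30, 4, 50))
  r_hand <- cor(rank(A[, "t1"]), rank(B[, "c1"]))
  R <- cor(cbind(A, B), method = "spearman")
  expect_equal(R["t1", "c1"], r_hand, tolerance = 1e-12)
  # monotone transform leaves the edge set unchanged
  e1 <- spearman_clr_network(A, B, r_min = 0.5, fdr_max = 1, n_boot = 0,
                             loo_screen = FALSE)
  e2 <- spearman_clr_network(A, exp(B), r_min = 0.5, fdr_max = 1, n_boot = 0,
                             loo_screen = FALSE)
  expect_equal(e1$r, e2$r, tolerance = 1e-12)
})

test_that("an anti-coupled planted pair yields a negative cross edge", {
  lay <- taxa_layout(sim_config())
  tx <- lay$taxon[order(abs(lay$base - 0.6))][1]
  cs <- data.frame(factor = "f1", taxon = tx, cell = "Th17", loading = -1.5)
  cfg <- sim_config(seed = 71, coupling_spec = cs)
  sim <- simulate_coupled(cfg)
  cm <- clr(replace_zeros(closure(t(sim$taxa$counts))))
  ci <- do.call(cbind, lapply(sibling_blocks(sim$gating$tree), function(b)
    clr(replace_zeros(closure(sim$gating$proportions[, b, drop = FALSE])))))
  edges <- spearman_clr_network(cm, ci, r_min = 0.6, fdr_max = 0.01,
                                n_boot = 50, seed = 1)
  hit <- edges[(edges$source == tx & edges$target == "Th17") |
                 (edges$source == "Th17" & edges$target == tx), ]
  expect_equal(nrow(hit), 1)
  expect_lt(hit$r, -0.6)
  expect_equal(hit$sign, -1L)
  expect_gte(hit$bootstrap_support, 0.8)
})

test_that("network assembly is simple, typed, and threshold-consistent", {
  edges <- data.frame(source = c("taxA", "taxB"),
                      target = c("cellX", "cellX"),
                      weight = c(0.7, -0.65), method = "spearman")
  g <- build_network(edges, taxa = c("taxA", "taxB", "taxC"),
                     cells = c("cellX", "cellY"),
                     cell_tissue = c(cellX = "IEL", cellY = "SPLN"))
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::V(g)$type[igraph::V(g)$name %in%
                                      c("taxA", "taxB", "taxC")], "taxon")
  expect_equal(igraph::V(g)$tissue[igraph::V(g)$name == "cellX"], "IEL")
  # empty edge list keeps the declared node universe
  g0 <- build_network(edges[0, ], taxa = "t1", cells = "c1")
  expect_equal(igraph::vcount(g0), 2)
  expect_equal(igraph::ecount(g0), 0)
  # conflicting duplicate edges are an error
  dup <- rbind(edges, data.frame(source = "cellX", target = "taxA",
                                 weight = 0.2, method = "spearman"))
  expect_error(build_network(dup, taxa = c("taxA", "taxB"),
                             cells = "cellX"), "conflicting")
  expect_error(build_network(data.frame(source = "zz", target = "cellX",
                                        weight = 1),
                             taxa = "taxA", cells = "cellX"), "unknown")
})
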