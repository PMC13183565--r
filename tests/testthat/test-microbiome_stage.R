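test_that("retain-resolve matches the hand-worked 5-taxon fixture", {
  tab <- toy_counts()
  # A, B pass round 1; C, D individually fail but their genus passes round 2;
  # E ends in "other"
  rr <- retain_resolve(tab, prevalence_min = 0.5, abundance_min = 0.01,
                       glom_rank = "genus")
  rows <- rownames(rr$table$counts)
  expect_setequal(rows, c("A", "B", "glom:Bacteria;p1;c1;o1;f2;gCD", "other"))
  expect_equal(colSums(rr$table$counts), colSums(tab$counts))
  expect_equal(unname(rr$table$counts["other", ]), c(1, 0, 0, 0))
  expect_equal(unname(rr$audit),
               c(5, 2, 2, 1, 1))  # initial, round1, candidates, round2, other
  # audit partitions the taxa: every input taxon assigned exactly once
  expect_setequal(names(rr$assignment), rownames(tab$counts))
  expect_false(any(is.na(rr$assignment)))
})

test_that("vacuous thresholds retain everything", {
  tab <- toy_counts()
  rr <- retain_resolve(tab, prevalence_min = 0, abundance_min = 0)
  expect_equal(unname(rr$audit["other_merged"]), 0)
  expect_equal(nrow(rr$table$counts), nrow(tab$counts))
  expect_error(retain_resolve(tab, glom_rank = "strain"), "unknown rank")
})

test_that("mass conservation holds on simulated data", {
  tab <- simulate_microbiome(sim_config(seed = 8))
  rr <- retain_resolve(tab, prevalence_min = 0.4, abundance_min = 0.005)
  expect_equal(colSums(rr$table$counts), colSums(tab$counts))
  a <- rr$audit
  expect_equal(unname(a["retained_round2"] + a["other_merged"]),
               unname(a["glommed_candidates"]))
})

test_that("alpha diversity reproduces closed-form values", {
  cnt <- cbind(u = c(10, 10, 10, 10), s = c(5, 0, 0, 0))
  rownames(cnt) <- paste0("t", 1:4)
  tab <- taxa_count_table(cnt, rep("k;p;c;o;f;g;s", 4),
                          data.frame(timepoint = factor(c("t1", "t1"),
                                                        ordered = TRUE),
                                     sex = c("F", "M"),
                                     row.names = c("u", "s")))
  expect_equal(unname(alpha_diversity(tab, "shannon")),
               c(log(4), 0), tolerance = 1e-12)
  expect_equal(unname(alpha_diversity(tab, "inv_simpson")), c(4, 1))
  expect_equal(unname(alpha_diversity(tab, "richness")), c(4, 1))
  # maximum-entropy bound
  tab2 <- simulate_microbiome(sim_config(seed = 12))
  expect_true(all(alpha_diversity(tab2, "shannon") <=
                    log(alpha_diversity(tab2, "richness")) + 1e-12))
})

test_that("alpha trend model matches the normal-equations oracle", {
  tab <- simulate_microbiome(sim_config(seed = 13))
  sh <- alpha_diversity(tab, "shannon")
  res <- test_alpha_trend(sh, tab$metadata)
  X <- model.matrix(~ timepoint + sex,
                    data.frame(timepoint = factor(tab$metadata$timepoint,
                                                  ordered = FALSE),
                               sex = factor(tab$metadata$sex)))
  beta <- solve(t(X) %*% X) %*% t(X) %*% sh
  expect_equal(unname(res$coefficients), unname(drop(beta)),
               tolerance = 1e-10)
  # constant response: F ~ 0, p ~ 1
  const <- setNames(rep(2, length(sh)), names(sh))
  res0 <- test_alpha_trend(const, tab$metadata)
  expect_true(all(res0$anova$`Pr(>F)`[1:2] > 0.99))
})

test_that("beta distances match standard formula evaluations", {
  cnt <- t(rbind(a = c(0.5, 0.5, 0) * 100, b = c(0.25, 0.25, 0.5) * 100))
  storage.mode(cnt) <- "integer"
  rownames(cnt) <- paste0("t", 1:3)
  md <- data.frame(timepoint = factor(c("x", "y"), ordered = TRUE),
                   sex = c("F", "M"), row.names = c("a", "b"))
  tab <- taxa_count_table(cnt, rep("k;p;c;o;f;g;s", 3), md)
  bc <- beta_distance(tab, "bray_curtis")
  expect_equal(bc["a", "b"], 0.5)
  jc <- beta_distance(tab, "jaccard")
  expect_gt(jc["a", "b"], 0)  # one taxon absent in a
  ai <- beta_distance(tab, "aitchison")
  expect_equal(ai["a", "a"], 0)
  expect_equal(ai, t(ai))
  # identical samples at distance 0; disjoint supports at 1
  cnt2 <- t(rbind(s1 = c(10L, 0L, 5L), s2 = c(10L, 0L, 5L),
                  s3 = c(0L, 7L, 0L)))
  rownames(cnt2) <- paste0("t", 1:3)
  tab2 <- taxa_count_table(cnt2, rep("k;p;c;o;f;g;s", 3),
                           data.frame(timepoint = factor(c("x", "x", "y"),
                                                         ordered = TRUE),
                                      sex = c("F", "M", "F"),
                                      row.names = paste0("s", 1:3)))
  for (m in c("jaccard", "bray_curtis")) {
    d <- beta_distance(tab2, m)
    expect_equal(d["s1", "s2"], 0)
    expect_equal(d["s1", "s3"], 1)
  }
})

test_that("PCoA recovers Euclidean geometry", {
  x <- c(0, 1, 2, 3.5, 7)
  d <- as.matrix(dist(cbind(x)))
  ord <- pcoa(d, k = 2)
  expect_equal(abs(cor(ord$coordinates[, 1], x)), 1, tolerance = 1e-10)
  # distances among recovered coordinates reproduce the input (Euclidean)
  set.seed(4)
  Y <- matrix(rnorm(30), 10, 3)
  dY <- as.matrix(dist(Y))
  oY <- pcoa(dY, k = 9)
  rec <- as.matrix(dist(oY$coordinates))
  expect_lt(max(abs(rec - dY)), 1e-8)
  expect_true(all(diff(oY$eigenvalues) <= 1e-9))
  expect_error(pcoa(dY, k = 10), "k must be")
})

test_that("PERMANOVA pseudo-F matches a direct sums-of-squares oracle", {
  set.seed(5)
  X <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(X))
  g <- factor(rep(c("a", "b"), each = 3))
  res <- permanova(d, g, n_perm = 199, seed = 2, pairwise_gate = 1.1)
  # Anderson partition computed directly from the distance matrix
  n <- 6
  sst <- sum(d[lower.tri(d)]^2) / n
  ssw <- 0
  for (lv in levels(g)) {
    idx <- which(g == lv)
    dd <- d[idx, idx]
    ssw <- ssw + sum(dd[lower.tri(dd)]^2) / length(idx)
  }
  f_oracle <- ((sst - ssw) / 1) / (ssw / (n - 2))
  expect_equal(res$pseudo_F, f_oracle, tolerance = 1e-10)
  expect_true(res$R2 >= 0 && res$R2 <= 1)
})

test_that("clearly separated duplicated groups reach the minimal p-value", {
  # groups large enough that partition-preserving permutations (which tie
  # exactly) are vanishingly unlikely among the drawn permutations
  set.seed(99)
  base <- rbind(matrix(0, 10, 2), matrix(10, 10, 2))
  d <- as.matrix(dist(base + matrix(rnorm(40, 0, 1e-6), 20)))
  g <- rep(c("lo", "hi"), each = 10)
  res <- permanova(d, g, n_perm = 199, seed = 3)
  expect_equal(res$p, 1 / 200)
  expect_false(is.null(res$pairwise))
  expect_equal(nrow(res$pairwise), 1)
})

test_that("PERMANOVA is invariant to sample reordering", {
  set.seed(6)
  X <- matrix(rnorm(24), 12, 2)
  d <- as.matrix(dist(X))
  g <- factor(rep(c("a", "b", "c"), each = 4))
  r1 <- permanova(d, g, n_perm = 99, seed = 1)
  pm <- sample.int(12)
  r2 <- permanova(d[pm, pm], g[pm], n_perm = 99, seed = 1)
  expect_equal(r1$pseudo_F, r2$pseudo_F, tolerance = 1e-10)
  expect_equal(r1$R2, r2$R2, tolerance = 1e-10)
})
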