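test_that("orthogonal polynomial contrasts handle equal and unequal spacing", {
  eq <- polynomial_contrasts(c(1, 2, 3, 4), degree = 1)
  expect_equal(drop(eq) / max(abs(eq)), c(-3, -1, 1, 3) / 3, tolerance = 1e-10)
  ages <- c(7, 14, 24, 56)
  lin <- polynomial_contrasts(ages, degree = 1)
  centered <- ages - mean(ages)  # (-18.25, -11.25, -1.25, 30.75)
  expect_equal(drop(lin), centered / sqrt(sum(centered^2)), tolerance = 1e-10)
  full <- polynomial_contrasts(ages, degree = 3)
  expect_equal(full %*% t(full), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(full)), rep(0, 3), tolerance = 1e-10)
  expect_error(polynomial_contrasts(c(7, 7, 24)), "duplicate")
  expect_error(polynomial_contrasts(ages, degree = 4), "degree")
})

test_that("reverse difference contrasts estimate sequential changes", {
  m <- reverse_difference_contrasts(4, labels = c("P7", "P14", "P24", "W8"))
  expect_equal(rownames(m), c("P14-P7", "P24-P14", "W8-P24"))
  expect_equal(unname(m %*% c(1, 2, 4, 8)), cbind(c(1, 2, 4)))
  expect_equal(unname(rowSums(m)), rep(0, 3))
  expect_error(reverse_difference_contrasts(1), ">= 2")
})

test_that("BH adjustment matches a brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  brute_bh <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    q <- rep(NA_real_, n); running <- Inf
    for (i in seq_len(n)) {
      idx <- o[i]; rank <- n - i + 1
      running <- min(running, p[idx] * n / rank)
      q[idx] <- min(1, running)
    }
    q
  }
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("half-sample mode finds the densest region", {
  x <- c(rnorm(50, 0, 0.05), 3, 4, 5)
  expect_lt(abs(codamia:::half_sample_mode(x)), 0.2)
  expect_equal(codamia:::half_sample_mode(c(2, 4)), 3)
})

test_that("CLR model is exactly invariant to per-sample depth scaling", {
  tab <- simulate_microbiome(sim_config(seed = 31))
  a1 <- fit_da_clr(tab)
  scaled <- tab
  fac <- rep(1L, ncol(scaled$counts)); fac[seq(1, 48, by = 3)] <- 7L
  scaled$counts <- sweep(scaled$counts, 2, fac, "*")
  a2 <- fit_da_clr(scaled)
  expect_equal(a1$pairwise$effect, a2$pairwise$effect, tolerance = 1e-8)
  expect_equal(a1$pairwise$p, a2$pairwise$p, tolerance = 1e-8)
})

test_that("offset model absorbs known per-sample sampling fractions", {
  # constructed fixture with large counts everywhere, so the pseudocount is
  # negligible and the true offsets are exactly the injected log factors
  set.seed(32)
  n_tax <- 30; n_smp <- 24
  base <- exp(rnorm(n_tax, 8, 0.6))
  counts <- matrix(rpois(n_tax * n_smp, base), n_tax, n_smp)
  counts <- counts + 200L
  rownames(counts) <- paste0("t", seq_len(n_tax))
  colnames(counts) <- paste0("s", seq_len(n_smp))
  md <- data.frame(
    timepoint = factor(rep(c("a", "b", "c", "d"), each = 6), ordered = TRUE),
    sex = rep(c("F", "M"), 12), age = rep(c(7, 14, 24, 56), each = 6),
    row.names = colnames(counts))
  tab <- taxa_count_table(counts, rep("k;p;c;o;f;g;s", n_tax), md)
  b1 <- fit_da_offset(tab)
  scaled <- tab
  fac <- rep(1L, n_smp); fac[seq(2, n_smp, by = 4)] <- 5L
  scaled$counts <- sweep(scaled$counts, 2, fac, "*")
  b2 <- fit_da_offset(scaled)
  expect_equal(b1$pairwise$effect, b2$pairwise$effect, tolerance = 5e-3)
  # offsets are identified only up to per-cell constants (the cell-means
  # design absorbs any per-cell shift), so compare after centering the true
  # log factors within each timepoint x sex cell
  d <- b2$offsets - b1$offsets
  cells <- interaction(md$timepoint, md$sex)
  center_within <- function(v) v - ave(v, cells)
  expect_equal(unname(center_within(d)),
               unname(center_within(log(fac))), tolerance = 5e-3)
})

test_that("consensus is the thresholded intersection of the two models", {
  tab <- simulate_microbiome(sim_config(seed = 33))
  a <- fit_da_clr(tab); b <- fit_da_offset(tab)
  cs <- consensus(a, b, alpha_q = 0.01, effect_min = 1)
  key <- function(d) paste(d$taxon, d$contrast)
  sigA <- key(a$pairwise[a$pairwise$q < 0.01 & abs(a$pairwise$effect) > 1, ])
  sigB <- key(b$pairwise[b$pairwise$q < 0.01 & abs(b$pairwise$effect) > 1, ])
  expect_setequal(key(cs$calls), intersect(sigA, sigB))
  # tightening thresholds (weakly) shrinks the set
  cs2 <- consensus(a, b, alpha_q = 0.001, effect_min = 1.5)
  expect_true(all(key(cs2$calls) %in% key(cs$calls)))
  # mismatched taxon universes are refused
  b_sub <- b
  b_sub$taxa <- b$taxa[-1]
  expect_error(consensus(a, b_sub), "different taxa")
})

test_that("consensus drops sub-threshold effects even when both models agree", {
  fake <- function(effect) {
    pw <- data.frame(taxon = "t1", contrast = "c1", effect = effect,
                     se = 0.1, p = 1e-6, q = 1e-6)
    structure(list(model_id = "x", taxa = "t1",
                   global = data.frame(taxon = "t1", F = 1, p = 1e-6,
                                       q = 1e-6),
                   pairwise = pw, converged = TRUE),
              class = "da_result")
  }
  expect_equal(nrow(consensus(fake(0.5), fake(0.5))$calls), 0)
  expect_equal(nrow(consensus(fake(2), fake(2))$calls), 1)
})
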