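test_that("Dirichlet log-likelihood matches closed forms", {
  # Dirichlet(1,1,1): density is Gamma(3) = 2 everywhere on the simplex
  for (y in list(c(0.2, 0.3, 0.5), c(0.6, 0.3, 0.1))) {
    expect_equal(dirichlet_loglik(rbind(y), rep(1, 3) / 3, 3), log(2),
                 tolerance = 1e-12)
  }
  # k = 2 reduces to the beta density
  y <- 0.37; mu <- 0.6; phi <- 11
  expect_equal(dirichlet_loglik(rbind(c(1 - y, y)), c(1 - mu, mu), phi),
               dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE),
               tolerance = 1e-12)
  expect_error(dirichlet_loglik(rbind(c(0, 1)), c(0.5, 0.5), 2), "boundary")
})

test_that("Dirichlet density integrates to one over the simplex (quadrature)", {
  mu <- c(0.25, 0.35, 0.4); phi <- 7
  h <- 1 / 400
  grid <- expand.grid(y1 = seq(h / 2, 1, by = h), y2 = seq(h / 2, 1, by = h))
  grid <- grid[grid$y1 + grid$y2 < 1, ]
  dens <- exp(vapply(seq_len(nrow(grid)), function(i) {
    y <- c(grid$y1[i], grid$y2[i])
    dirichlet_loglik(rbind(c(y, 1 - sum(y))), mu, phi)
  }, numeric(1)))
  expect_equal(sum(dens) * h^2, 1, tolerance = 2e-3)
})

test_that("beta regression recovers simulated parameters", {
  ok <- 0; runs <- 20
  for (s in seq_len(runs)) {
    set.seed(300 + s)
    n <- 200
    x <- rnorm(n)
    mu <- plogis(-1 + 1 * x)
    phi <- 20
    y <- rbeta(n, mu * phi, (1 - mu) * phi)
    fit <- fit_beta_regression(y, cbind(1, x))
    est <- c(fit$beta[1, ], fit$gamma)
    se <- sqrt(diag(fit$vcov))
    ok <- ok + all(abs(est - c(-1, 1, log(20))) < 3 * se)
  }
  expect_gte(ok / runs, 0.9)
})

test_that("intercept-only beta fit tracks the sample mean and ML dominates truth", {
  set.seed(11)
  y1 <- rbeta(80, 2, 6); y2 <- rbeta(80, 6, 2)
  f1 <- fit_beta_regression(y1, matrix(1, 80))
  f2 <- fit_beta_regression(y2, matrix(1, 80))
  expect_lt(plogis(f1$beta[1, 1]), plogis(f2$beta[1, 1]))
  expect_equal(unname(plogis(f1$beta[1, 1])), mean(y1), tolerance = 0.05)
  # log-likelihood at the optimum is >= log-likelihood at the truth
  ll_true <- dirichlet_loglik(cbind(1 - y1, y1), c(0.75, 0.25), 8)
  expect_gte(f1$loglik, ll_true - 1e-8)
})

test_that("Dirichlet regression is equivariant to component relabeling", {
  set.seed(12)
  n <- 150
  Y <- shrink_composition(closure(matrix(rgamma(n * 3, c(2, 3, 5)), n,
                                         byrow = TRUE)))
  colnames(Y) <- c("a", "b", "c")
  X <- matrix(1, n)
  f1 <- fit_dirichlet_regression(Y, X)
  f2 <- fit_dirichlet_regression(Y[, c("b", "c", "a")], X)
  mu1 <- colMeans(f1$mu)[c("b", "c", "a")]
  mu2 <- colMeans(f2$mu)
  expect_equal(unname(mu1), unname(mu2), tolerance = 1e-4)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_error(fit_dirichlet_regression(Y[, 1:2], X), "beta regression")
})

test_that("mean-coefficient bias shrinks as n grows", {
  bias_at <- function(n, reps = 8) {
    err <- 0
    for (s in seq_len(reps)) {
      set.seed(1000 * n + s)
      x <- rnorm(n)
      eta <- cbind(0, -0.5 + 0.8 * x, 0.3 - 0.4 * x)
      mu <- exp(eta) / rowSums(exp(eta))
      phi <- 25
      Y <- t(vapply(seq_len(n), function(i) {
        g <- rgamma(3, mu[i, ] * phi); g / sum(g)
      }, numeric(3)))
      fit <- fit_dirichlet_regression(shrink_composition(Y), cbind(1, x))
      err <- err + abs(fit$beta[1, 2] - 0.8)
    }
    err / reps
  }
  expect_lt(bias_at(800), bias_at(50) + 0.02)
})

test_that("partition check splits planted positive correlation and not Dirichlet noise", {
  # common Dirichlet: negative dependence in expectation, no split
  set.seed(21)
  splits <- 0
  for (s in 1:40) {
    G <- matrix(rgamma(60 * 3, c(3, 4, 5)), 60, byrow = TRUE)
    Y <- G / rowSums(G)
    splits <- splits + check_subtree_partition(Y)$split
  }
  expect_lte(splits / 40, 0.15)  # near the nominal one-sided alpha
  # planted shared factor between components 1 and 2
  set.seed(22)
  z <- rnorm(80)
  eta <- cbind(z, z, rnorm(80, 2, 0.3))
  E <- exp(eta + matrix(rnorm(240, 0, 0.2), 80))
  Y2 <- E / rowSums(E)
  colnames(Y2) <- c("c1", "c2", "c3")
  pc <- check_subtree_partition(Y2)
  expect_true(pc$split)
  expect_true(any(vapply(pc$blocks, function(b)
    setequal(b, c("c1", "c2")), logical(1))))
  # two components never split
  expect_false(check_subtree_partition(Y2[, 1:2])$split)
})

test_that("global statistic is additive over sub-trees and localizes effects", {
  g <- simulate_cytometry(sim_config(seed = 41))
  nt <- nested_global_test(g)
  expect_equal(nt$lambda_overall, sum(nt$subtree_stats$LRT), tolerance = 1e-12)
  expect_equal(nt$df, sum(nt$subtree_stats$df))
  expect_gte(nt$lambda_overall, 0)
  # default config plants strong age trends: the global test must fire
  expect_lt(nt$p, 1e-6)
  # localization: effect planted only on the root T/B split
  loc <- 0
  for (s in 1:15) {
    cfg <- sim_config(seed = 500 + s, tree_effect_scale = 0)
    cfg$tree_spec[[1]]$effects[, "Tcell"] <- c(0, 0.5, 1, 1.5)
    gg <- simulate_cytometry(cfg)
    st <- suppressWarnings(nested_global_test(gg))$subtree_stats
    loc <- loc + (st$node[which.min(st$p)] == "CD45")
  }
  expect_gte(loc / 15, 0.9)
})

test_that("follow-up contrasts flag the planted interval and respect the gate", {
  hits <- miss <- 0
  for (s in 1:10) {
    cfg <- sim_config(seed = 600 + s, tree_effect_scale = 0)
    cfg$tree_spec[[2]]$effects[, "CD8SP"] <- c(0, 0, 1.5, 1.5)  # P14 -> P24 jump
    g <- simulate_cytometry(cfg)
    fu <- followup_contrasts(g, gate = FALSE)
    sig <- fu[fu$significant, ]
    hits <- hits + any(sig$node == "CD8SP" & sig$interval == "P24-P14")
    miss <- miss + any(sig$node == "CD8SP" & sig$interval == "W8-P24")
  }
  expect_gte(hits / 10, 0.9)
  expect_lte(miss / 10, 0.2)
  # q-values equal brute-force BH within the tissue family
  cfg <- sim_config(seed = 611)
  g <- simulate_cytometry(cfg)
  fu <- followup_contrasts(g, gate = FALSE)
  expect_equal(fu$q, p.adjust(fu$p, "BH"), tolerance = 1e-12)
  # gate: a null global test suppresses the contrasts
  nullish <- list(p = 0.9)
  expect_message(out <- followup_contrasts(g, global = nullish, gate = TRUE),
                 "not significant")
  expect_equal(nrow(out), 0)
})
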