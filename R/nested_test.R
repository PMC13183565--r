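#' Positive-correlation partition check for a sibling block
#'
#' The nested compositional framework assumes the components tested together
#' at a node are negatively interdependent (their fractions compete for the
#' same parent). This check computes all pairwise Pearson correlations of the
#' child fractions and, when any pair is significantly positive (one-sided
#' test at `alpha`), groups the positively co-varying components into
#' sub-blocks (connected components of the significant-positive-pair graph)
#' so the node can be tested as a two-level sub-tree: between blocks, then
#' within each block after renormalization.
#'
#' @param Y sample x k matrix of child fractions at one node (k >= 2).
#' @param alpha one-sided significance level for the positive-correlation
#'   test (default 0.05).
#' @return list: `split` (logical), `blocks` (list of component name
#'   vectors), `positive_pairs` (data frame of significant pairs).
#' @export
check_subtree_partition <- function(Y, alpha = 0.05) {
  Y <- as.matrix(Y)
  k <- ncol(Y)
  nm <- colnames(Y)
  if (is.null(nm)) nm <- colnames(Y) <- paste0("c", seq_len(k))
  if (k == 2)
    return(list(split = FALSE, blocks = list(nm),
                positive_pairs = NULL))
  pairs <- utils::combn(k, 2)
  sig <- logical(ncol(pairs))
  rr <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ct <- stats::cor.test(Y[, a], Y[, b], alternative = "greater")
    rr[i] <- unname(ct$estimate)
    sig[i] <- ct$p.value < alpha
  }
  if (!any(sig))
    return(list(split = FALSE, blocks = list(nm), positive_pairs = NULL))
  adj <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in which(sig)) {
    adj[pairs[1, i], pairs[2, i]] <- 1
    adj[pairs[2, i], pairs[1, i]] <- 1
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  blocks <- split(nm, comp)
  names(blocks) <- NULL
  pp <- data.frame(a = nm[pairs[1, sig]], b = nm[pairs[2, sig]],
                   r = rr[sig], stringsAsFactors = FALSE)
  list(split = TRUE, blocks = blocks, positive_pairs = pp)
}

# compositional units to test at one sibling block, after the partition
# check: either the block itself, or (on a split) the block-sum level plus
# each multi-member sub-block renormalized.
partition_units <- function(Y, alpha = 0.05) {
  pc <- check_subtree_partition(Y, alpha)
  if (!pc$split)
    return(list(units = list(Y), partition = pc))
  blocks <- pc$blocks
  top <- vapply(blocks, function(b)
    rowSums(Y[, b, drop = FALSE]), numeric(nrow(Y)))
  colnames(top) <- vapply(blocks, paste, "", collapse = "+")
  units <- list(top)
  for (b in blocks) {
    if (length(b) >= 2) {
      sub <- Y[, b, drop = FALSE]
      units[[length(units) + 1L]] <- closure(sub)
    }
  }
  list(units = units, partition = pc)
}

# fit one compositional unit under null (intercept) and full (intercept +
# timepoint polynomial contrasts) mean models; returns LRT, df, p. The
# precision phi is estimated once under the null and held fixed in both
# likelihood evaluations (profile/known-variance form): letting the
# saturated mean model re-estimate phi biases the ratio liberal at study
# sample sizes, while the null phi is consistent under H0.
fit_unit_lrt <- function(Y, Xfull) {
  n <- nrow(Y)
  k <- ncol(Y)
  Y <- shrink_composition(closure(Y))
  X0 <- Xfull[, 1, drop = FALSE]
  null_fit <- fit_dirichlet_core(Y, X0)
  # warm-start the full model at the null optimum so LRT >= 0 by construction
  p <- ncol(Xfull)
  b0 <- matrix(0, k - 1, p)
  b0[, 1] <- null_fit$beta[, 1]
  full_fit <- fit_dirichlet_core(Y, Xfull, start = as.vector(b0),
                                 fixed_gamma = null_fit$gamma)
  lrt <- max(0, 2 * (full_fit$loglik - null_fit$loglik))
  df <- (k - 1) * (p - 1)
  list(lrt = lrt, df = df,
       p = stats::pchisq(lrt, df, lower.tail = FALSE),
       converged = null_fit$converged && full_fit$converged,
       null_fit = null_fit, full_fit = full_fit)
}

# sample-level design of age-weighted polynomial contrasts for a factor
poly_design <- function(timepoint, ages, degree = NULL) {
  tp <- factor(timepoint, ordered = FALSE)
  k <- nlevels(tp)
  if (is.null(degree)) degree <- k - 1L
  ages <- sort(unique(ages))
  P <- polynomial_contrasts(ages, degree = degree)
  X <- cbind(`(Intercept)` = 1, t(P)[as.integer(tp), , drop = FALSE])
  rownames(X) <- NULL
  X
}

#' Global nested compositional test over a gating tree
#'
#' Tests whether the composition anywhere in the gating tree changes with an
#' ordered factor (timepoint). Each sibling block of the tree is a
#' conditionally independent compositional unit; blocks with three or more
#' components are first screened for positively correlated components and
#' partitioned into two-level sub-trees where needed. Each unit is fitted by
#' beta (2 parts) or Dirichlet (3+ parts) regression under the null (common
#' mean composition for all groups) and the full model (mean depends on the
#' factor through age-weighted polynomial contrasts); the unit
#' likelihood-ratio statistics and degrees of freedom are summed into the
#' global statistic Lambda_overall, referred to a chi-squared distribution.
#'
#' @param gating a [gating_dataset()].
#' @param degree polynomial degree for the timepoint effect (default:
#'   number of levels - 1, the saturated trend).
#' @param partition_alpha significance level of the positive-correlation
#'   partition screen.
#' @return object of class `nested_test_result`: `lambda_overall`, `df`,
#'   `p`, per-unit `subtree_stats`, and `partition_log`.
#' @export
nested_global_test <- function(gating, degree = NULL,
                               partition_alpha = 0.05) {
  stopifnot(inherits(gating, "gating_dataset"))
  md <- gating$metadata
  if (nlevels(factor(md$timepoint)) < 2)
    stop("nested_global_test: need >= 2 factor levels")
  Xfull <- poly_design(md$timepoint, md$age, degree)
  stats_rows <- list()
  partition_log <- list()
  for (b in sibling_blocks(gating$tree)) {
    Y <- gating$proportions[, b, drop = FALSE]
    pu <- partition_units(Y, alpha = partition_alpha)
    node <- gating$tree$parent[match(b[1], gating$tree$node)]
    if (pu$partition$split)
      partition_log[[node]] <- pu$partition$blocks
    for (u in seq_along(pu$units)) {
      Yu <- pu$units[[u]]
      res <- tryCatch(fit_unit_lrt(Yu, Xfull), error = function(e) NULL)
      unit_name <- if (length(pu$units) > 1)
        paste0(node, "/unit", u) else node
      if (is.null(res) || !res$converged) {
        warning("nested_global_test: sub-tree '", unit_name,
                "' not fittable; excluded (df adjusted)")
        next
      }
      stats_rows[[length(stats_rows) + 1L]] <-
        data.frame(node = unit_name, k = ncol(Yu), LRT = res$lrt,
                   df = res$df, p = res$p, stringsAsFactors = FALSE)
    }
  }
  st <- do.call(rbind, stats_rows)
  lambda <- sum(st$LRT)
  df <- sum(st$df)
  structure(list(lambda_overall = lambda, df = df,
                 p = stats::pchisq(lambda, df, lower.tail = FALSE),
                 subtree_stats = st,
                 partition_log = partition_log),
            class = "nested_test_result")
}

#' @export
print.nested_test_result <- function(x, ...) {
  cat(sprintf("Nested compositional global test: Lambda_overall = %.3f, df = %d, p = %.3g\n",
              x$lambda_overall, x$df, x$p))
  print(x$subtree_stats, row.names = FALSE)
  if (length(x$partition_log))
    cat("partitioned nodes:", paste(names(x$partition_log),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Sequential-interval follow-up contrasts
#'
#' After a significant global test, regresses each gated population's
#' fraction-of-parent individually on timepoint (beta regression with a
#' cell-means design) and Wald-tests the reverse-difference contrasts
#' (sequential timepoint differences on the logit scale). P-values are
#' BH-adjusted within tissue.
#'
#' @param gating a [gating_dataset()].
#' @param global optional `nested_test_result`; when supplied and `gate` is
#'   TRUE, contrasts run only if its p-value is below `gate_alpha`.
#' @param gate logical; gate on global significance (default TRUE).
#' @param gate_alpha global-test significance gate (default 0.05).
#' @param fdr significance label threshold on q (default 0.05).
#' @return data frame: tissue, node, interval, estimate (logit change), se,
#'   z, p, q, direction, significant.
#' @export
followup_contrasts <- function(gating, global = NULL, gate = TRUE,
                               gate_alpha = 0.05, fdr = 0.05) {
  stopifnot(inherits(gating, "gating_dataset"))
  if (gate && !is.null(global) && global$p >= gate_alpha) {
    message("followup_contrasts: global test not significant; no contrasts")
    return(data.frame())
  }
  md <- gating$metadata
  tp <- factor(md$timepoint, ordered = FALSE)
  k <- nlevels(tp)
  X <- stats::model.matrix(~ 0 + tp)
  colnames(X) <- levels(tp)
  L <- reverse_difference_contrasts(k, labels = levels(tp))
  tissue <- if (!is.null(md$tissue)) as.character(md$tissue[1]) else "all"
  rows <- list()
  for (b in sibling_blocks(gating$tree)) {
    for (node in b) {
      y <- gating$proportions[, node]
      fit <- tryCatch(fit_beta_regression(shrink_composition(
        cbind(1 - y, y))[, 2], X), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      bmean <- fit$beta[1, ]                  # logit-scale level means
      Vb <- fit$vcov[seq_len(k), seq_len(k)]
      est <- drop(L %*% bmean)
      se <- sqrt(diag(L %*% Vb %*% t(L)))
      z <- est / se
      rows[[length(rows) + 1L]] <-
        data.frame(tissue = tissue, node = node, interval = rownames(L),
                   estimate = est, se = se, z = z,
                   p = 2 * stats::pnorm(-abs(z)),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # BH within tissue (single tissue per dataset, but grouped for generality)
  out$q <- NA_real_
  for (ts in unique(out$tissue))
    out$q[out$tissue == ts] <- bh_adjust(out$p[out$tissue == ts])
  out$direction <- ifelse(out$estimate > 0, "increase", "decrease")
  out$significant <- out$q < fdr
  out
}
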