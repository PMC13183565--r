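#' Retain-resolve taxon denoising
#'
#' Two-round filter-and-agglomerate denoising of a taxon count table.
#' Round 1 retains, at native resolution, every taxon meeting both a
#' prevalence criterion (non-zero in at least `prevalence_min` of samples)
#' and a mean relative-abundance criterion (`abundance_min`). The remaining
#' taxa are agglomerated (counts summed) to `glom_rank`, the same criteria
#' are re-applied to the glommed groups, and passers are retained at the
#' coarser rank. Everything still failing is summed into a single "other"
#' row. Per-sample totals are conserved exactly and every input taxon ends up
#' in exactly one output row.
#'
#' @param table a [taxa_count_table()].
#' @param prevalence_min minimum fraction of samples with a non-zero count,
#'   in [0, 1); default 0.10; 0 disables the filter.
#' @param abundance_min minimum mean relative abundance, in [0, 1);
#'   default 1e-4 (0.01%); 0 disables the filter.
#' @param glom_rank rank to agglomerate to in round 2; one of the seven
#'   standard ranks; default "genus".
#' @return list of class `retain_resolve_result`: `table` (denoised
#'   [taxa_count_table()]), `audit` (named counts: initial, retained_round1,
#'   glommed_candidates, retained_round2, other_merged), and `assignment`
#'   (output row per input taxon).
#' @export
retain_resolve <- function(table, prevalence_min = 0.10,
                           abundance_min = 1e-4, glom_rank = "genus") {
  stopifnot(inherits(table, "taxa_count_table"))
  if (prevalence_min < 0 || prevalence_min >= 1 ||
      abundance_min < 0 || abundance_min >= 1)
    stop("retain_resolve: thresholds must lie in [0, 1)")
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  ri <- match(glom_rank, ranks)
  if (is.na(ri)) stop("retain_resolve: unknown rank '", glom_rank, "'")
  counts <- table$counts
  if (!nrow(counts) || !ncol(counts)) stop("retain_resolve: empty table")
  rel <- t(closure(t(counts)))
  passes <- function(m, relm) {
    prev <- rowMeans(m > 0)
    mra <- rowMeans(relm)
    prev >= prevalence_min & mra >= abundance_min
  }
  keep1 <- passes(counts, rel)
  retained1 <- counts[keep1, , drop = FALSE]
  assignment <- stats::setNames(rep(NA_character_, nrow(counts)),
                                rownames(counts))
  assignment[keep1] <- rownames(counts)[keep1]
  rest <- rownames(counts)[!keep1]
  glom_tab <- NULL
  n_glom <- 0L
  n_ret2 <- 0L
  n_other_groups <- 0L
  other <- NULL
  if (length(rest)) {
    lin <- strsplit(table$lineage[rest], ";", fixed = TRUE)
    key <- vapply(lin, function(p) paste(p[seq_len(ri)], collapse = ";"), "")
    groups <- split(rest, key)
    n_glom <- length(groups)
    gm <- t(vapply(groups, function(tx)
      colSums(counts[tx, , drop = FALSE]), numeric(ncol(counts))))
    rownames(gm) <- paste0("glom:", names(groups))
    grel <- sweep(gm, 2, colSums(counts), "/")
    keep2 <- passes(gm, grel)
    n_ret2 <- sum(keep2)
    glom_tab <- gm[keep2, , drop = FALSE]
    for (g in which(keep2))
      assignment[groups[[g]]] <- rownames(gm)[g]
    fail <- which(!keep2)
    n_other_groups <- length(fail)
    if (length(fail)) {
      other <- colSums(gm[fail, , drop = FALSE])
      for (g in fail) assignment[groups[[g]]] <- "other"
    }
  }
  out <- retained1
  lineage_out <- table$lineage[rownames(retained1)]
  if (!is.null(glom_tab) && nrow(glom_tab)) {
    out <- rbind(out, glom_tab)
    pad <- function(key) {
      p <- strsplit(sub("^glom:", "", key), ";", fixed = TRUE)[[1]]
      paste(c(p, rep("NA", 7 - length(p))), collapse = ";")
    }
    lineage_out <- c(lineage_out,
                     vapply(rownames(glom_tab), pad, ""))
  }
  if (!is.null(other)) {
    out <- rbind(out, other = other)
    lineage_out <- c(lineage_out, other = paste(rep("other", 7),
                                                collapse = ";"))
  }
  audit <- c(initial = nrow(counts),
             retained_round1 = sum(keep1),
             glommed_candidates = n_glom,
             retained_round2 = n_ret2,
             other_merged = n_other_groups)
  res <- list(table = taxa_count_table(out, unname(lineage_out),
                                       table$metadata),
              audit = audit, assignment = assignment)
  class(res) <- "retain_resolve_result"
  res
}

#' @export
print.retain_resolve_result <- function(x, ...) {
  a <- x$audit
  cat("retain-resolve:", a["initial"], "taxa ->", a["retained_round1"],
      "retained (round 1),", a["retained_round2"], "glommed (round 2)")
  if (a["other_merged"] > 0)
    cat(",", a["other_merged"], "failed group(s) merged into 'other'")
  cat("\n")
  invisible(x)
}

#' Alpha diversity
#'
#' Shannon index (-sum p log p, natural log), inverse Simpson (1 / sum p^2),
#' or richness (number of non-zero taxa) per sample.
#'
#' @param table a [taxa_count_table()].
#' @param metric one of "shannon", "inv_simpson", "richness".
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table,
                            metric = c("shannon", "inv_simpson",
                                       "richness")) {
  stopifnot(inherits(table, "taxa_count_table"))
  metric <- match.arg(metric)
  m <- t(table$counts)
  switch(metric,
         shannon = vegan::diversity(m, index = "shannon"),
         inv_simpson = vegan::diversity(m, index = "invsimpson"),
         richness = vegan::specnumber(m))
}

#' Linear trend test for an alpha-diversity metric
#'
#' Ordinary least squares of a per-sample metric on timepoint and sex main
#' effects, with sequential F-tests per term.
#'
#' @param values named numeric vector (names = sample ids).
#' @param metadata data frame with `timepoint` and `sex` for those samples.
#' @return list: `fit` (the `lm`), `anova` (per-term F table), and
#'   `coefficients`.
#' @export
test_alpha_trend <- function(values, metadata) {
  md <- metadata[names(values), , drop = FALSE]
  if (nlevels(factor(md$timepoint)) < 2 || nlevels(factor(md$sex)) < 2)
    stop("test_alpha_trend: need >= 2 levels of timepoint and sex")
  df <- data.frame(y = as.numeric(values),
                   timepoint = factor(md$timepoint, ordered = FALSE),
                   sex = factor(md$sex))
  fit <- stats::lm(y ~ timepoint + sex, data = df)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    aliased <- names(which(is.na(stats::coef(fit))))
    stop("test_alpha_trend: rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  degenerate <- stats::var(df$y) < 1e-24
  an <- if (degenerate) suppressWarnings(stats::anova(fit))
  else stats::anova(fit)
  if (degenerate) {
    # constant response: no variance to explain, define F = 0, p = 1
    nt <- nrow(an) - 1L
    an$`F value`[seq_len(nt)] <- 0
    an$`Pr(>F)`[seq_len(nt)] <- 1
  }
  list(fit = fit, anova = an, coefficients = stats::coef(fit))
}

#' Beta-diversity distance matrix
#'
#' Jaccard (presence/absence), Bray-Curtis (relative abundance) or Aitchison
#' (Euclidean distance of CLR vectors; zeros replaced multiplicatively first)
#' distances between samples.
#'
#' @param table a [taxa_count_table()].
#' @param metric one of "jaccard", "bray_curtis", "aitchison".
#' @param delta zero-replacement value for the Aitchison metric (default half
#'   the smallest positive relative abundance).
#' @return symmetric sample x sample matrix with attribute `metric`.
#' @export
beta_distance <- function(table,
                          metric = c("jaccard", "bray_curtis", "aitchison"),
                          delta = NULL) {
  stopifnot(inherits(table, "taxa_count_table"))
  metric <- match.arg(metric)
  rel <- closure(t(table$counts))
  d <- switch(metric,
              jaccard = as.matrix(vegan::vegdist(rel > 0, method = "jaccard",
                                                 binary = TRUE)),
              bray_curtis = as.matrix(vegan::vegdist(rel, method = "bray")),
              aitchison = aitchison_dist_matrix(replace_zeros(rel, delta)))
  attr(d, "metric") <- metric
  d
}

#' Principal coordinate analysis
#'
#' Classic metric scaling (Gower double-centering + eigendecomposition) of a
#' distance matrix; coordinates are scaled by the square root of their
#' eigenvalue. Axes with negative eigenvalues are dropped but the full
#' eigenvalue spectrum is reported.
#'
#' @param dist symmetric distance matrix.
#' @param k number of axes to return (< number of samples).
#' @return list: `coordinates` (sample x k), `eigenvalues` (all, decreasing),
#'   `variance_explained` (fractions over positive eigenvalues).
#' @export
pcoa <- function(dist, k = 2) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (k >= n) stop("pcoa: k must be < number of samples")
  sc <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  eig <- sort(sc$eig, decreasing = TRUE)
  pos <- eig[eig > 1e-12]
  co <- sc$points
  colnames(co) <- paste0("PCo", seq_len(ncol(co)))
  list(coordinates = co, eigenvalues = eig,
       variance_explained = pos / sum(pos))
}

#' PERMANOVA with pairwise follow-up
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (Anderson's pseudo-F partition of within/between sums of squared
#' distances, permutation p-value), with pairwise group comparisons run only
#' when the omnibus p-value passes `pairwise_gate` (BH-adjusted).
#'
#' @param dist symmetric sample x sample distance matrix.
#' @param groups factor-like group labels, one per sample (in matrix order).
#' @param n_perm number of permutations (>= 99 recommended).
#' @param seed integer seed for the permutation stream.
#' @param pairwise_gate omnibus p-value threshold gating the pairwise stage.
#' @return object of class `permanova_result`: pseudo_F, R2, p, n_perm and a
#'   `pairwise` data frame (groupA, groupB, pseudo_F, p, q) or NULL.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1,
                      pairwise_gate = 0.01) {
  d <- as.matrix(dist)
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("permanova: need >= 2 groups with >= 2 samples each")
  if (n_perm < 99) warning("permanova: n_perm < 99 gives coarse p-values")
  dd <- stats::as.dist(d)
  set.seed(seed)
  fit <- vegan::adonis2(dd ~ groups, permutations = n_perm)
  res <- list(pseudo_F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1],
              n_perm = n_perm, pairwise = NULL)
  if (!is.na(res$p) && res$p < pairwise_gate) {
    lv <- levels(groups)
    prs <- utils::combn(lv, 2, simplify = FALSE)
    rows <- lapply(prs, function(pr) {
      sel <- groups %in% pr
      sub <- stats::as.dist(d[sel, sel])
      g <- droplevels(groups[sel])
      f <- vegan::adonis2(sub ~ g, permutations = n_perm)
      data.frame(groupA = pr[1], groupB = pr[2], pseudo_F = f$F[1],
                 p = f$`Pr(>F)`[1], stringsAsFactors = FALSE)
    })
    pw <- do.call(rbind, rows)
    pw$q <- bh_adjust(pw$p)
    res$pairwise <- pw
  }
  class(res) <- "permanova_result"
  res
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d perms)\n",
              x$pseudo_F, x$R2, x$p, x$n_perm))
  if (!is.null(x$pairwise)) {
    cat("pairwise comparisons (BH-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Nonparametric richness estimate (Chao1-type)
#'
#' A simple stand-in richness estimator based on singleton and doubleton
#' counts: S_obs + f1^2 / (2 f2) (bias-corrected form when f2 = 0). Useful
#' for sensitivity checks of richness-based conclusions; it is a basic
#' abundance-based estimator, not a full mixture-model richness fit.
#'
#' @param table a [taxa_count_table()].
#' @return named numeric vector of estimated richness per sample.
#' @export
richness_estimate <- function(table) {
  stopifnot(inherits(table, "taxa_count_table"))
  apply(table$counts, 2, function(x) {
    s <- sum(x > 0); f1 <- sum(x == 1); f2 <- sum(x == 2)
    if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
  })
}
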