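#' Orthogonal polynomial contrasts on actual ages
#'
#' Builds degree-1..`degree` orthogonal polynomial contrasts on the real (in
#' general unequally spaced) ages of the timepoints, by Gram-Schmidt
#' orthonormalization of powers of the centered ages. With unequal spacing
#' the linear contrast is simply the normalized centered ages, so the
#' contrast weights the levels by how far apart they actually are in days.
#'
#' @param ages strictly increasing numeric vector of level ages.
#' @param degree highest polynomial degree (< number of levels).
#' @return degree x length(ages) matrix; rows orthonormal, each summing to 0.
#' @examples
#' polynomial_contrasts(c(7, 14, 24, 56), degree = 1)
#' @export
polynomial_contrasts <- function(ages, degree = length(ages) - 1L) {
  if (anyDuplicated(ages)) stop("polynomial_contrasts: duplicate ages")
  if (is.unsorted(ages)) stop("polynomial_contrasts: ages must be increasing")
  k <- length(ages)
  if (degree >= k) stop("polynomial_contrasts: degree must be < #levels")
  # columns of contr.poly(scores=) are the Gram-Schmidt orthonormal polys
  cp <- stats::contr.poly(k, scores = ages)
  m <- t(cp[, seq_len(degree), drop = FALSE])
  rownames(m) <- colnames(cp)[seq_len(degree)]
  colnames(m) <- names(ages)
  m
}

#' Reverse difference contrasts
#'
#' k-1 contrasts over an ordered factor with k levels; row i estimates
#' level_{i+1} - level_i, i.e. the change across each sequential interval
#' (P14 - P7, P24 - P14, ...).
#'
#' @param k_levels number of levels (>= 2).
#' @param labels optional level labels used to name the rows.
#' @return (k-1) x k matrix; rows sum to 0.
#' @export
reverse_difference_contrasts <- function(k_levels, labels = NULL) {
  if (k_levels < 2) stop("reverse_difference_contrasts: need >= 2 levels")
  m <- matrix(0, k_levels - 1L, k_levels)
  for (i in seq_len(k_levels - 1L)) {
    m[i, i] <- -1
    m[i, i + 1L] <- 1
  }
  if (!is.null(labels)) {
    colnames(m) <- labels
    rownames(m) <- paste(labels[-1], labels[-k_levels], sep = "-")
  } else {
    rownames(m) <- paste0("L", 2:k_levels, "-L", 1:(k_levels - 1L))
  }
  m
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (clipped at 1, monotone in p rank).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# half-sample mode: midpoint of the shortest window containing ceiling(n/2)
# points; robust, deterministic estimate of the densest region of the
# cross-taxon coefficient distribution (the compositional bias).
half_sample_mode <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n <= 2L) return(mean(x))
  h <- ceiling(n / 2)
  w <- x[h:n] - x[1:(n - h + 1L)]
  i <- which.min(w)
  (x[i] + x[i + h - 1L]) / 2
}

# cell structure for the DA engines: timepoint x sex cells (sex collapses
# when only one level is present), with per-cell sizes and timepoint ages
da_cells <- function(metadata) {
  tp <- factor(metadata$timepoint, ordered = FALSE)
  sx <- factor(metadata$sex)
  cells <- if (nlevels(sx) > 1) interaction(tp, sx, drop = TRUE) else tp
  n_g <- as.vector(table(cells))
  if (any(n_g < 2))
    stop("differential abundance: every timepoint x sex cell needs >= 2 samples")
  tp_of_cell <- tp[match(levels(cells), cells)]
  ages <- metadata$age
  if (is.null(ages)) ages <- as.integer(tp)
  ages <- sort(unique(ages))
  names(ages) <- levels(tp)
  list(cells = cells, n = n_g, tp_of_cell = tp_of_cell,
       levels = levels(tp), ages = ages)
}

# per-taxon cell means and variances of a samples x taxa response matrix
cell_moments <- function(Y, cells) {
  G <- nlevels(cells)
  idx <- split(seq_len(nrow(Y)), cells)
  m <- matrix(NA_real_, G, ncol(Y), dimnames = list(levels(cells),
                                                    colnames(Y)))
  v <- m
  for (g in seq_len(G)) {
    Yg <- Y[idx[[g]], , drop = FALSE]
    m[g, ] <- colMeans(Yg)
    v[g, ] <- apply(Yg, 2, stats::var)
  }
  list(m = m, v = v)
}

# contrast machinery shared by the two DA engines. Group variances are
# allowed to differ (the first timepoint is genuinely noisier), so pairwise
# reverse-difference contrasts use Welch t-tests with Satterthwaite degrees
# of freedom and the global polynomial trend uses the Johansen (Welch-James)
# approximate F. Cell variances are first squeezed halfway toward the
# cell's mean variance across taxa: with few replicates per cell and
# zero-imputed values collapsing to near-constants, raw variances of
# low-abundance taxa underestimate their sampling noise. The cross-taxon
# half-sample mode of each contrast estimate is subtracted as the
# compositional bias term.
da_contrast_tests <- function(mom, cells, bias_correct = TRUE,
                              moderate = TRUE) {
  if (moderate) {
    # empirical-Bayes squeeze of each cell's variances toward an
    # abundance-dependent trend (limma); no df credit is taken, so the
    # moderation only stabilizes collapsed variance estimates of sparse,
    # zero-imputed taxa without anti-conservative df inflation
    dg <- cells$n - 1
    for (g in seq_along(dg)) {
      sq <- tryCatch(
        limma::squeezeVar(mom$v[g, ], df = dg[g], covariate = mom$m[g, ]),
        error = function(e) NULL)
      if (!is.null(sq)) mom$v[g, ] <- sq$var.post
    }
  }
  K <- length(cells$levels)
  poly <- polynomial_contrasts(cells$ages, degree = min(3L, K - 1L))
  rev <- reverse_difference_contrasts(K, labels = cells$levels)
  # map timepoint-level contrasts to cell weights (averaging over sexes)
  tp_idx <- as.integer(cells$tp_of_cell)
  cells_per_tp <- as.vector(table(tp_idx))
  to_cells <- function(Lt) {
    Lc <- Lt[, tp_idx, drop = FALSE] / rep(cells_per_tp[tp_idx],
                                           each = nrow(Lt))
    Lc
  }
  Lr <- to_cells(rev)
  Lp <- to_cells(poly)
  m <- mom$m; v <- mom$v; n_g <- cells$n
  vg <- v / n_g                                  # G x taxa
  est_r <- Lr %*% m
  est_p <- Lp %*% m
  if (bias_correct) {
    est_r <- est_r - apply(est_r, 1, half_sample_mode)
    est_p <- est_p - apply(est_p, 1, half_sample_mode)
  }
  var_r <- (Lr^2) %*% vg
  se_r <- sqrt(var_r)
  df_r <- var_r^2 / ((Lr^4) %*% (vg^2 / (n_g - 1)))
  p_r <- 2 * stats::pt(-abs(est_r / se_r), df = df_r)
  q <- nrow(Lp)
  nt <- ncol(m)
  Fstat <- p_global <- numeric(nt)
  for (t in seq_len(nt)) {
    R <- Lp %*% (vg[, t] * t(Lp))
    Rinv <- tryCatch(solve(R), error = function(e) NULL)
    if (is.null(Rinv)) {
      Fstat[t] <- NA_real_; p_global[t] <- NA_real_
      next
    }
    W <- drop(crossprod(est_p[, t], Rinv %*% est_p[, t]))
    a_g <- vg[, t] * colSums(Lp * (Rinv %*% Lp))   # tr(Rinv R_g) per cell
    A <- sum(a_g^2 / (n_g - 1))
    cJ <- q + 2 * A - 6 * A / (q + 2)
    df2 <- q * (q + 2) / (3 * A)
    Fstat[t] <- W / cJ
    p_global[t] <- stats::pf(Fstat[t], q, df2, lower.tail = FALSE)
  }
  list(effect = est_r, se = se_r, p_pairwise = p_r,
       F_global = Fstat, p_global = p_global,
       contrasts = rownames(rev))
}

da_result <- function(model_id, taxa, ct, converged = TRUE) {
  pw <- lapply(seq_along(ct$contrasts), function(i) {
    data.frame(taxon = taxa, contrast = ct$contrasts[i],
               effect = ct$effect[i, ] / log(2),
               se = ct$se[i, ] / log(2),
               p = ct$p_pairwise[i, ],
               q = bh_adjust(ct$p_pairwise[i, ]),
               stringsAsFactors = FALSE)
  })
  structure(list(model_id = model_id,
                 taxa = taxa,
                 global = data.frame(taxon = taxa, F = ct$F_global,
                                     p = ct$p_global,
                                     q = bh_adjust(ct$p_global),
                                     stringsAsFactors = FALSE),
                 pairwise = do.call(rbind, pw),
                 converged = converged),
            class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat("DA model", x$model_id, "-", length(x$taxa), "taxa;",
      sum(x$global$q < 0.01), "taxa with global-trend q < 0.01\n")
  if (!x$converged) cat("NOTE: offset iteration did not converge\n")
  invisible(x)
}

#' Differential abundance, CLR model with coefficient-mode bias correction
#'
#' Per-taxon ordinary least squares of CLR-transformed relative abundance on
#' a timepoint (cell-means) + sex design. Counts are closed to proportions
#' first (making the model exactly invariant to per-sample depth), zeros are
#' replaced multiplicatively, and the CLR transform is applied. Compositional
#' bias is corrected by subtracting, per contrast, the half-sample mode of
#' the contrast estimate across taxa (the densest value, attributed to the
#' common compositional offset rather than to true change). Because group
#' variances genuinely differ across development (neonatal samples are
#' shallower and noisier), pairwise reverse-difference intervals use Welch
#' t-tests with Satterthwaite degrees of freedom and the global trend uses
#' the Johansen (Welch-James) approximate F over age-weighted polynomial
#' contrasts; effects are reported in log2 units, q-values are BH within
#' contrast.
#'
#' @param table a [taxa_count_table()].
#' @param delta zero-replacement value on the proportion scale (default half
#'   the smallest positive proportion; scale-free).
#' @param bias_correct subtract the cross-taxon coefficient mode (default
#'   TRUE).
#' @return a `da_result` (model_id "A_clr_bias").
#' @export
fit_da_clr <- function(table, delta = NULL, bias_correct = TRUE) {
  stopifnot(inherits(table, "taxa_count_table"))
  cells <- da_cells(table$metadata)
  comp <- closure(t(table$counts))
  Y <- clr(replace_zeros(comp, delta))          # samples x taxa
  ct <- da_contrast_tests(cell_moments(Y, cells$cells), cells,
                          bias_correct = bias_correct)
  da_result("A_clr_bias", colnames(Y), ct)
}

#' Differential abundance, log-count model with sample-fraction offsets
#'
#' Per-taxon linear model on log(count + 1) with a per-sample offset playing
#' the role of the unknown sampling fraction (log depth). Offsets are
#' estimated by alternating (1) per-taxon OLS given the offsets and (2)
#' updating each sample's offset by the median residual across taxa, until
#' the largest offset change is below `tol` (or `max_iter` is reached, in
#' which case the result is flagged, not fatal). Welch/Johansen tests on the
#' offset-adjusted cell means as in [fit_da_clr()]; effects in log2 units.
#'
#' @param table a [taxa_count_table()].
#' @param pseudocount added to counts before the log (default 1).
#' @param tol convergence tolerance on the offsets.
#' @param max_iter maximum alternations.
#' @return a `da_result` (model_id "B_offset_bias") with `converged` flag.
#' @export
fit_da_offset <- function(table, pseudocount = 1, tol = 1e-6,
                          max_iter = 50L) {
  stopifnot(inherits(table, "taxa_count_table"))
  cells <- da_cells(table$metadata)
  X <- stats::model.matrix(~ 0 + cells$cells)
  Y <- log(t(table$counts) + pseudocount)       # samples x taxa
  n <- nrow(X); p <- ncol(X)
  XtXinv <- solve(crossprod(X))
  o <- numeric(n)
  o_prev <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Yc <- Y - o
    B <- XtXinv %*% crossprod(X, Yc)
    R <- Yc - X %*% B
    delta_o <- apply(R, 1, stats::median)
    o_new <- o + delta_o
    o_new <- o_new - mean(o_new)                # identifiability
    if (max(abs(o_new - o)) < tol) {
      o <- o_new
      converged <- TRUE
      break
    }
    # the median alternation can settle on a 2-cycle; its midpoint is the
    # natural fixed point (the cycle's oscillation is orthogonal noise)
    if (!is.null(o_prev) && max(abs(o_new - o_prev)) < tol) {
      o <- (o_new + o) / 2
      converged <- TRUE
      break
    }
    o_prev <- o
    o <- o_new
  }
  Yc <- Y - o
  ct <- da_contrast_tests(cell_moments(Yc, cells$cells), cells)
  res <- da_result("B_offset_bias", colnames(Y), ct,
                   converged = converged)
  res$offsets <- o
  res
}

#' Consensus set of differentially abundant taxa
#'
#' Intersects the significant taxa of two differential-abundance models,
#' per reverse-difference interval: a taxon is a consensus call for an
#' interval when both models give BH q < `alpha_q` and |log2 effect| >
#' `effect_min` there. The consensus set is by construction a subset of each
#' model's significant set and shrinks as the thresholds tighten.
#'
#' @param resA,resB `da_result` objects over the same taxa.
#' @param alpha_q BH q-value threshold (default 0.01).
#' @param effect_min minimum |log2 effect| (default 1).
#' @return object of class `consensus_set`: data frame `calls` (taxon,
#'   contrast, effect per model) and the thresholds used.
#' @export
consensus <- function(resA, resB, alpha_q = 0.01, effect_min = 1) {
  stopifnot(inherits(resA, "da_result"), inherits(resB, "da_result"))
  if (!setequal(resA$taxa, resB$taxa))
    stop("consensus: the two models cover different taxa")
  key <- function(d) paste(d$taxon, d$contrast, sep = "\r")
  sig <- function(res) {
    d <- res$pairwise
    d[d$q < alpha_q & abs(d$effect) > effect_min, , drop = FALSE]
  }
  a <- sig(resA); b <- sig(resB)
  keep <- intersect(key(a), key(b))
  a2 <- a[match(keep, key(a)), c("taxon", "contrast", "effect")]
  b2 <- b[match(keep, key(b)), "effect"]
  calls <- if (length(keep)) {
    data.frame(a2, effect_B = b2, row.names = NULL,
               stringsAsFactors = FALSE)
  } else {
    data.frame(taxon = character(), contrast = character(),
               effect = numeric(), effect_B = numeric())
  }
  names(calls)[3] <- "effect_A"
  structure(list(calls = calls, alpha_q = alpha_q,
                 effect_min = effect_min),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat("consensus DA set:", nrow(x$calls), "taxon-interval calls (q <",
      x$alpha_q, ", |log2 effect| >", x$effect_min, ")\n")
  invisible(x)
}

#' Run the full consensus differential-abundance stage
#'
#' Convenience wrapper: fits both bias-corrected models and intersects their
#' significant sets.
#'
#' @inheritParams consensus
#' @param table a [taxa_count_table()] (typically retain-resolved).
#' @return list with `modelA`, `modelB`, `consensus`.
#' @export
consensus_da <- function(table, alpha_q = 0.01, effect_min = 1) {
  a <- fit_da_clr(table)
  b <- fit_da_offset(table)
  list(modelA = a, modelB = b,
       consensus = consensus(a, b, alpha_q, effect_min))
}
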