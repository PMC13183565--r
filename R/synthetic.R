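#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate a
#' postnatal co-development study in mice: four ordered timepoints (P7, P14,
#' P24 and 8 weeks; ages 7, 14, 24 and 56 days), both sexes, six replicates
#' per sex x timepoint cell, microbial succession in three waves (an early
#' Lactobacillaceae-like family declining as a Bacteroidaceae-like family
#' peaks mid-study and a Muribaculaceae-like family plateaus post-weaning),
#' lower sequencing depth and higher overdispersion at the first timepoint,
#' and a depth-4 gating tree (pan-marker, T/B split, CD4/CD8 quadrant,
#' functional quadrant) with planted age trends.
#'
#' @param timepoints named numeric vector of ages in days, strictly increasing.
#' @param n_per_group replicates per timepoint x sex cell (>= 2).
#' @param sexes sex labels.
#' @param seed integer seed; identical seed + config gives bit-identical data.
#' @param depth_per_timepoint mean sequencing depth per timepoint.
#' @param dm_precision Dirichlet-multinomial concentration total per timepoint
#'   (smaller = more overdispersed).
#' @param wave_amplitude peak log-abundance gain of each successional wave
#'   (0 gives a null microbiome with no age structure).
#' @param n_background number of non-wave background taxa.
#' @param taxa_per_wave taxa per successional family.
#' @param tree_effect_scale multiplier on the gating tree's planted age
#'   effects (0 gives a null cytometry dataset).
#' @param tree_precision Dirichlet precision at each gating node.
#' @param tissue tissue label stored in cytometry metadata.
#' @param coupling_spec data frame with columns `factor`, `taxon`, `cell`,
#'   `loading`: each row couples one taxon and one gated population through a
#'   shared per-sample latent Gaussian factor with the given loading on the
#'   log (taxon) and logit (cell) scales.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(timepoints = c(P7 = 7, P14 = 14, P24 = 24, W8 = 56),
                       n_per_group = 6,
                       sexes = c("F", "M"),
                       seed = 1L,
                       depth_per_timepoint = c(20000, 50000, 50000, 50000),
                       dm_precision = c(150, 400, 400, 400),
                       wave_amplitude = 3,
                       n_background = 36,
                       taxa_per_wave = 8,
                       tree_effect_scale = 1,
                       tree_precision = 60,
                       tissue = "IEL",
                       coupling_spec = NULL) {
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("sim_config: timepoint ages must be strictly increasing")
  if (n_per_group < 2) stop("sim_config: n_per_group must be >= 2")
  if (length(depth_per_timepoint) != length(timepoints) ||
      length(dm_precision) != length(timepoints))
    stop("sim_config: per-timepoint vectors must match timepoints")
  cfg <- list(
    timepoints = timepoints,
    n_per_group = as.integer(n_per_group),
    sexes = sexes,
    seed = as.integer(seed),
    depth_per_timepoint = depth_per_timepoint,
    dm_precision = dm_precision,
    wave_spec = default_wave_spec(wave_amplitude),
    n_background = n_background,
    taxa_per_wave = taxa_per_wave,
    tree_spec = default_tree_spec(tree_effect_scale,
                                  n_timepoints = length(timepoints),
                                  phi = tree_precision),
    tissue = tissue,
    coupling_spec = coupling_spec
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Successional wave specification
#'
#' Each wave is a Gaussian bump on the log-abundance scale over age: taxa of
#' `family` gain `amplitude` log units at `peak_age`, decaying with `width`
#' days. The defaults plant early dominance (peak at day 7), a mid-study
#' bloom (day 14), and a post-weaning plateau (broad bump centred at day 56).
#'
#' @param amplitude peak gain in log units (shared by the three waves).
#' @return data frame with columns family, peak_age, amplitude, width.
#' @export
default_wave_spec <- function(amplitude = 3) {
  data.frame(
    family = c("Lactobacillaceae", "Bacteroidaceae", "Muribaculaceae"),
    peak_age = c(7, 14, 56),
    amplitude = amplitude,
    width = c(8, 8, 30),
    stringsAsFactors = FALSE
  )
}

#' Default gating-tree specification
#'
#' A depth-4 tree: CD45+ root splits into T (CD3+) and B (CD19+) cells; T
#' cells into a CD4/CD8 quadrant; CD4+ cells into a FoxP3/RORgT functional
#' quadrant. Planted age effects (multinomial-logit scale, one row per
#' timepoint) emulate the expansion of T cells and CD8+ cells after weaning
#' and the post-weaning appearance of RORgT+ and FoxP3+RORgT+ (pTreg) cells.
#'
#' @param effect_scale multiplier on all planted effects.
#' @param n_timepoints number of timepoints the effect rows must cover.
#' @param phi Dirichlet precision at every node.
#' @return list of sibling-block specs (`parent`, `children`, `baseline`,
#'   `effects`, `phi`) with attribute `root`.
#' @export
default_tree_spec <- function(effect_scale = 1, n_timepoints = 4, phi = 60) {
  eff <- function(...) {
    m <- effect_scale * cbind(...)
    if (nrow(m) != n_timepoints)
      stop("default_tree_spec: effects need one row per timepoint")
    m
  }
  z <- rep(0, n_timepoints)
  spec <- list(
    list(parent = "CD45", children = c("Tcell", "Bcell"),
         baseline = c(0.45, 0.55),
         effects = eff(Tcell = c(0, 0.2, 1.0, 1.3)[seq_len(n_timepoints)],
                       Bcell = z),
         phi = phi),
    list(parent = "Tcell",
         children = c("CD4SP", "CD8SP", "DPos", "DNeg"),
         baseline = c(0.35, 0.15, 0.10, 0.40),
         effects = eff(CD4SP = z,
                       CD8SP = c(0, 0.2, 1.2, 1.5)[seq_len(n_timepoints)],
                       DPos = c(0, 0, 0.3, 0.3)[seq_len(n_timepoints)],
                       DNeg = z),
         phi = phi),
    list(parent = "CD4SP",
         children = c("Treg", "Th17", "pTreg", "FnNeg"),
         baseline = c(0.08, 0.05, 0.01, 0.86),
         effects = eff(Treg = z,
                       Th17 = c(0, 0, 1.5, 1.2)[seq_len(n_timepoints)],
                       pTreg = c(0, 0, 1.0, 1.2)[seq_len(n_timepoints)],
                       FnNeg = z),
         phi = phi)
  )
  attr(spec, "root") <- "CD45"
  spec
}

validate_sim_config <- function(cfg) {
  for (blk in cfg$tree_spec) {
    if (abs(sum(blk$baseline) - 1) > 1e-9)
      stop("sim_config: sibling baselines at '", blk$parent,
           "' do not sum to 1")
    if (length(blk$children) != length(blk$baseline) ||
        ncol(blk$effects) != length(blk$children))
      stop("sim_config: malformed block at '", blk$parent, "'")
  }
  all_nodes <- c(attr(cfg$tree_spec, "root"),
                 unlist(lapply(cfg$tree_spec, `[[`, "children")))
  if (anyDuplicated(all_nodes))
    stop("sim_config: tree_spec is not a tree (duplicate node)")
  for (blk in cfg$tree_spec) {
    if (!blk$parent %in% all_nodes)
      stop("sim_config: unknown parent '", blk$parent, "'")
  }
  layout <- taxa_layout(cfg)
  if (!is.null(cfg$coupling_spec)) {
    cs <- cfg$coupling_spec
    if (!all(c("factor", "taxon", "cell", "loading") %in% names(cs)))
      stop("sim_config: coupling_spec needs factor, taxon, cell, loading")
    if (!all(cs$taxon %in% layout$taxon))
      stop("sim_config: coupling references unknown taxon: ",
           paste(setdiff(cs$taxon, layout$taxon), collapse = ", "))
    if (!all(cs$cell %in% all_nodes))
      stop("sim_config: coupling references unknown cell population: ",
           paste(setdiff(cs$cell, all_nodes), collapse = ", "))
  }
  invisible(cfg)
}

#' Deterministic taxon layout of a simulation config
#'
#' Taxon names, family/genus assignments, wave membership and baseline
#' log-abundances are fixed functions of the config (no randomness), so taxa
#' can be referenced by name in coupling specs before any data are drawn.
#'
#' @param cfg a [sim_config()].
#' @return data frame: taxon, family, genus, wave (NA for background),
#'   base (baseline log abundance).
#' @export
taxa_layout <- function(cfg) {
  ws <- cfg$wave_spec
  rows <- list()
  for (i in seq_len(nrow(ws))) {
    fam <- ws$family[i]
    k <- cfg$taxa_per_wave
    genus <- paste0(substr(fam, 1, 5), "_g", rep(1:2, length.out = k))
    rows[[i]] <- data.frame(
      taxon = sprintf("%s_%s_s%02d", fam, genus, seq_len(k)),
      family = fam, genus = genus, wave = fam,
      base = -1, stringsAsFactors = FALSE)
  }
  nb <- cfg$n_background
  fam <- paste0("BgFamily", rep(1:6, length.out = nb))
  genus <- paste0(fam, "_g", rep(1:2, each = 3, length.out = nb))
  rows[[length(rows) + 1L]] <- data.frame(
    taxon = sprintf("%s_%s_s%02d", fam, genus, seq_len(nb)),
    family = fam, genus = genus, wave = NA_character_,
    base = seq(-1.5, 1.5, length.out = nb), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sample_frame <- function(cfg) {
  tp <- names(cfg$timepoints)
  grid <- expand.grid(rep = seq_len(cfg$n_per_group), sex = cfg$sexes,
                      timepoint = tp, stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("S%03d_%s_%s_r%d", seq_len(nrow(grid)),
                            grid$timepoint, grid$sex, grid$rep)
  grid$age <- cfg$timepoints[grid$timepoint]
  grid$timepoint <- factor(grid$timepoint, levels = tp, ordered = TRUE)
  rownames(grid) <- grid$sample_id
  grid
}

wave_gain <- function(layout, ws, age) {
  gain <- numeric(nrow(layout))
  for (i in seq_len(nrow(ws))) {
    in_wave <- !is.na(layout$wave) & layout$wave == ws$family[i]
    gain[in_wave] <- ws$amplitude[i] *
      exp(-(age - ws$peak_age[i])^2 / (2 * ws$width[i]^2))
  }
  gain
}

#' Simulate a microbiome count table
#'
#' Counts are Dirichlet-multinomial per sample: the expected log-abundance of
#' each taxon is its baseline plus its wave's Gaussian bump at the sample's
#' age; the softmax of these log-abundances is the Dirichlet mean, with a
#' per-timepoint precision (lower at the first timepoint, giving the higher
#' inter-sample variance seen in neonatal samples) and a per-timepoint
#' negative-binomial sequencing depth (also lowest at the first timepoint).
#'
#' @param cfg a [sim_config()].
#' @param perturb_log optional sample x taxon matrix added to log-abundances
#'   before closure (used to inject latent couplings).
#' @return a [taxa_count_table()]; ground-truth wave memberships are attached
#'   as attribute `layout`.
#' @export
simulate_microbiome <- function(cfg, perturb_log = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  simulate_microbiome_impl(cfg, perturb_log)
}

simulate_microbiome_impl <- function(cfg, perturb_log = NULL) {
  layout <- taxa_layout(cfg)
  sf <- sample_frame(cfg)
  nt <- nrow(layout)
  counts <- matrix(0L, nt, nrow(sf),
                   dimnames = list(layout$taxon, sf$sample_id))
  tp_idx <- as.integer(sf$timepoint)
  for (j in seq_len(nrow(sf))) {
    lm <- layout$base + wave_gain(layout, cfg$wave_spec, sf$age[j])
    if (!is.null(perturb_log)) lm <- lm + perturb_log[j, ]
    mu <- exp(lm - max(lm))
    mu <- mu / sum(mu)
    alpha <- mu * cfg$dm_precision[tp_idx[j]]
    g <- stats::rgamma(nt, shape = alpha, rate = 1)
    if (all(g == 0)) g[which.max(alpha)] <- 1
    p <- g / sum(g)
    depth <- 0L
    while (depth <= 0L)
      depth <- stats::rnbinom(1, mu = cfg$depth_per_timepoint[tp_idx[j]],
                              size = 10)
    counts[, j] <- stats::rmultinom(1, depth, p)[, 1]
  }
  lineage <- sprintf("Bacteria;P_%s;C_%s;O_%s;%s;%s;%s",
                     layout$family, layout$family, layout$family,
                     layout$family, layout$genus, layout$taxon)
  tab <- taxa_count_table(counts, lineage,
                          sf[, c("timepoint", "sex", "age")])
  attr(tab, "layout") <- layout
  tab
}

#' Simulate a hierarchical gating dataset
#'
#' For each sample and internal gating node, child fractions-of-parent are
#' drawn from a Dirichlet distribution whose mean is the softmax of the node's
#' log-baseline plus its planted per-timepoint effect, at the node's stated
#' precision. Fractions multiply down the tree consistently and the root
#' fraction is 1.
#'
#' @param cfg a [sim_config()].
#' @param perturb_logit optional sample x node matrix added on the
#'   multinomial-logit scale before sampling (latent couplings).
#' @return a [gating_dataset()].
#' @export
simulate_cytometry <- function(cfg, perturb_logit = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  simulate_cytometry_impl(cfg, perturb_logit)
}

simulate_cytometry_impl <- function(cfg, perturb_logit = NULL) {
  sf <- sample_frame(cfg)
  spec <- cfg$tree_spec
  root <- attr(spec, "root")
  nodes <- c(root, unlist(lapply(spec, `[[`, "children")))
  parent <- c(NA_character_,
              unlist(lapply(spec, function(b)
                rep(b$parent, length(b$children)))))
  tree <- data.frame(node = nodes, parent = parent, stringsAsFactors = FALSE)
  P <- matrix(0, nrow(sf), length(nodes),
              dimnames = list(sf$sample_id, nodes))
  P[, root] <- 1
  tp_idx <- as.integer(sf$timepoint)
  for (j in seq_len(nrow(sf))) {
    for (blk in spec) {
      eta <- log(blk$baseline) + blk$effects[tp_idx[j], ]
      if (!is.null(perturb_logit))
        eta <- eta + perturb_logit[j, blk$children]
      mu <- exp(eta - max(eta))
      mu <- mu / sum(mu)
      g <- stats::rgamma(length(mu), shape = mu * blk$phi, rate = 1)
      if (all(g == 0)) g[which.max(mu)] <- 1
      P[j, blk$children] <- g / sum(g)
    }
  }
  md <- sf[, c("timepoint", "sex", "age")]
  md$tissue <- cfg$tissue
  gating_dataset(tree, P, md)
}

#' Simulate coupled microbiome and cytometry datasets
#'
#' Draws one standard-normal latent factor per factor id in the coupling spec
#' and per sample, and adds `loading * factor` to the coupled taxon's
#' log-abundance and the coupled population's multinomial logit before the
#' compositional sampling of [simulate_microbiome()] and
#' [simulate_cytometry()]. Because the injection happens on the log/logit
#' scale before closure, the planted association survives the CLR transform
#' and is recoverable by the integration stage. The loading's magnitude sets
#' the coupling strength on both sides; its sign sets the direction of the
#' cell-side response (negative loadings plant anti-coupled pairs).
#'
#' @param cfg a [sim_config()] with a non-empty `coupling_spec`.
#' @return list with elements `taxa` (a [taxa_count_table()]), `gating`
#'   (a [gating_dataset()]) and `truth` (latent factors and the coupling
#'   table).
#' @export
simulate_coupled <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cs <- cfg$coupling_spec
  if (is.null(cs) || !nrow(cs))
    stop("simulate_coupled: coupling_spec must be non-empty")
  set.seed(cfg$seed + 2L)
  sf <- sample_frame(cfg)
  layout <- taxa_layout(cfg)
  fac_ids <- unique(cs$factor)
  Z <- matrix(stats::rnorm(nrow(sf) * length(fac_ids)), nrow(sf),
              dimnames = list(sf$sample_id, fac_ids))
  perturb_taxa <- matrix(0, nrow(sf), nrow(layout),
                         dimnames = list(sf$sample_id, layout$taxon))
  nodes <- c(attr(cfg$tree_spec, "root"),
             unlist(lapply(cfg$tree_spec, `[[`, "children")))
  perturb_nodes <- matrix(0, nrow(sf), length(nodes),
                          dimnames = list(sf$sample_id, nodes))
  for (i in seq_len(nrow(cs))) {
    z <- Z[, as.character(cs$factor[i])]
    perturb_taxa[, cs$taxon[i]] <- perturb_taxa[, cs$taxon[i]] +
      abs(cs$loading[i]) * z
    perturb_nodes[, cs$cell[i]] <- perturb_nodes[, cs$cell[i]] +
      cs$loading[i] * z
  }
  set.seed(cfg$seed)
  taxa <- simulate_microbiome_impl(cfg, perturb_log = perturb_taxa)
  set.seed(cfg$seed + 1L)
  gating <- simulate_cytometry_impl(cfg, perturb_logit = perturb_nodes)
  list(taxa = taxa, gating = gating,
       truth = list(factors = Z, spec = cs))
}
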