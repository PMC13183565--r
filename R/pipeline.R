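#' Run the full synthetic analysis workflow
#'
#' Executes the pipeline stages in dependency order from one configuration:
#' `simulate` (coupled microbiome + cytometry synthetic data), `microbiome`
#' (alpha/beta diversity, PCoA, PERMANOVA), `da` (retain-resolve +
#' consensus differential abundance), `cytometry` (nested global test +
#' follow-up contrasts), `integrate` (USS transform, Mantel test,
#' proportionality and Spearman-CLR networks) and `validate` (topology +
#' Erdos-Renyi null comparison). Every output file is checksummed into the
#' returned manifest; identical config + seed reproduces identical
#' checksums. A stage whose upstream output is missing fails with an error
#' naming the missing stage.
#'
#' @param config a [default_pipeline_config()].
#' @return list of class `pipeline_run`: per-stage results, `manifest`
#'   (file, md5) and the `config` used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  files <- character()
  has <- function(stage) stage %in% config$stages
  need <- function(stage, from) {
    if (is.null(res[[stage]]))
      stop("run_pipeline: stage '", from, "' needs missing output of '",
           stage, "'")
  }
  if (has("simulate")) {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    if (is.null(sim_args$coupling_spec)) {
      cfg0 <- do.call(sim_config, sim_args)
      lay <- taxa_layout(cfg0)
      sim_args$coupling_spec <- data.frame(
        factor = c("f1", "f2"),
        taxon = lay$taxon[c(1, 10)],
        cell = c("Treg", "Th17"),
        loading = c(1.5, 1.5), stringsAsFactors = FALSE)
    }
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_coupled(scfg)
    res$simulate <- sim
    files <- c(files,
               write_count_table(sim$taxa,
                                 file.path(config$out_dir, "taxa")),
               write_gating_csv(sim$gating,
                                file.path(config$out_dir, "gating")))
  }
  if (has("microbiome")) {
    need("simulate", "microbiome")
    tab <- res$simulate$taxa
    alpha <- data.frame(
      sample_id = colnames(tab$counts),
      shannon = alpha_diversity(tab, "shannon"),
      inv_simpson = alpha_diversity(tab, "inv_simpson"),
      richness = alpha_diversity(tab, "richness"))
    d <- beta_distance(tab, "aitchison")
    ord <- pcoa(d, k = 2)
    pmv <- permanova(d, tab$metadata$timepoint, n_perm = config$n_perm,
                     seed = config$seed)
    res$microbiome <- list(alpha = alpha, dist = d, pcoa = ord,
                           permanova = pmv)
    f <- file.path(config$out_dir, "alpha_diversity.tsv")
    utils::write.table(alpha, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  if (has("da")) {
    need("simulate", "da")
    rr <- retain_resolve(res$simulate$taxa,
                         prevalence_min = config$retain_prevalence,
                         abundance_min = config$retain_abundance)
    cda <- consensus_da(rr$table, alpha_q = config$alpha_q,
                        effect_min = config$effect_min)
    res$da <- list(retain_resolve = rr, consensus = cda)
    f <- file.path(config$out_dir, "consensus_da.tsv")
    utils::write.table(cda$consensus$calls, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  if (has("cytometry")) {
    need("simulate", "cytometry")
    g <- res$simulate$gating
    glob <- nested_global_test(g)
    fu <- followup_contrasts(g, global = glob)
    res$cytometry <- list(global = glob, followup = fu)
    f <- file.path(config$out_dir, "nested_test.tsv")
    utils::write.table(glob$subtree_stats, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  if (has("integrate")) {
    need("da", "integrate")
    need("cytometry", "integrate")
    tab <- res$da$retain_resolve$table
    g <- res$simulate$gating
    comp <- closure(t(tab$counts))
    clr_micro <- clr(replace_zeros(comp))
    uss <- uss_transform(g)
    mt <- mantel_test(aitchison_dist_matrix(replace_zeros(comp)),
                      as.matrix(stats::dist(uss)),
                      n_perm = config$n_perm,
                      strata = tab$metadata$sex, seed = config$seed)
    blocks <- sibling_blocks(g$tree)
    clr_imm <- do.call(cbind, lapply(blocks, function(b)
      clr(replace_zeros(closure(g$proportions[, b, drop = FALSE])))))
    rho <- proportionality_rho(cbind(clr_micro, clr_imm))
    sp <- spearman_clr_network(clr_micro, clr_imm, r_min = config$r_min,
                               fdr_max = config$fdr_max, n_boot = 0,
                               seed = config$seed)
    idx <- which(upper.tri(rho) & rho > config$rho_cutoff, arr.ind = TRUE)
    rho_edges <- data.frame(source = rownames(rho)[idx[, 1]],
                            target = colnames(rho)[idx[, 2]],
                            weight = rho[idx], method = "rho",
                            stringsAsFactors = FALSE)
    net <- build_network(rho_edges, taxa = colnames(clr_micro),
                         cells = colnames(clr_imm))
    res$integrate <- list(mantel = mt, rho = rho, rho_edges = rho_edges,
                          spearman_edges = sp, network = net, uss = uss)
    f <- file.path(config$out_dir, "network.graphml")
    write_network(net, f)
    f2 <- file.path(config$out_dir, "edges.tsv")
    utils::write.table(rho_edges, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f, f2)
  }
  if (has("validate")) {
    need("integrate", "validate")
    net <- res$integrate$network
    topo <- topology_summary(net)
    cmp <- if (topo$n_edges > 0)
      null_compare(net, B = config$n_null, seed = config$seed)
    else NULL
    res$validate <- list(topology = topo, null = cmp)
    if (!is.null(cmp)) {
      f <- file.path(config$out_dir, "null_comparison.tsv")
      utils::write.table(cmp$comparison, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
    }
  }
  res$manifest <- data.frame(file = unname(files),
                             md5 = unname(tools::md5sum(files)),
                             stringsAsFactors = FALSE)
  class(res) <- "pipeline_run"
  res
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run:", paste(x$config$stages, collapse = " -> "), "\n")
  cat(nrow(x$manifest), "output files in", x$config$out_dir, "\n")
  invisible(x)
}
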