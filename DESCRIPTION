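Package: codamia
Title: Compositional Analysis of Co-Developing Microbiome and Immune Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end compositional data analysis (CoDA) pipeline for studies
    that profile the gut microbiome and flow-cytometry T-cell repertoires in the
    same animals across postnatal development. Provides compositional primitives
    (closure, multiplicative zero replacement, centered log-ratio transform,
    Aitchison distance, and the unzeroing-stabilization-standardization transform
    for gated cytometry data); retain-resolve taxon denoising; alpha/beta diversity
    with PERMANOVA; consensus differential abundance from two bias-corrected
    log-linear models with weighted polynomial and reverse-difference contrasts;
    beta and Dirichlet regression (alternative mean/precision parameterization) on
    hierarchical gating trees with a summed global likelihood-ratio statistic;
    Mantel tests, proportionality and Spearman-CLR association networks with
    permutation FDR control; and random-graph validation of network topology
    against Erdos-Renyi nulls. A seeded synthetic-data generator with planted
    successional waves, gating-tree age trends, and latent microbe-immune
    couplings makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
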