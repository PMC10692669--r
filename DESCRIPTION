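Package: phosnet
Title: Kinase Signaling Networks from Perturbation Phosphoproteomics and
    Spatial Interaction Statistics for Imaging Mass Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs patient-level kinase signaling networks from
    inhibitor-perturbation phosphoproteomics: fragment-level filtering and
    imputation, phosphosite-level differential abundance, site-centric signed
    enrichment against directional phosphosite signatures (kinase activity
    scores), and extraction of perturbation subnetworks from a prior causal
    signaling network by bounded shortest paths with phosphosite-guided
    pruning, centralities and mutation overrepresentation tests. A spatial
    branch computes Voronoi neighborhood graphs from segmented-cell tables,
    permutation-based attraction/avoidance statistics with Stouffer cohort
    meta-combination, and PD1+/PDL1+ microaggregate analysis. Protein-complex
    co-abundance and mRNA-protein correlation utilities, plus seeded
    synthetic-data generators with ground-truth sidecars for every input, make
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    graphics,
    grDevices,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
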