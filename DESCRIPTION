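Package: repsig
Title: Immune Repertoire Diversity, Similarity and Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of adaptive immune repertoire (TCR and BCR IgH)
    clonotype tables from paired tumor and adjacent non-tumor tissue.
    Reads AIRR Rearrangement and MiXCR-style exports, applies productive
    clonotype filters, and computes richness, normalized Shannon diversity
    entropy (NSDE), Morisita-Horn similarity (MHSI), V(D)J gene-usage
    ordination (PCA/MDS), B-cell somatic hypermutation clone-network
    statistics (average degree and its degree-1-pruned variant), paired and
    unpaired cohort statistics with exact small-sample tests, and
    Kaplan-Meier survival stratified by repertoire features. Includes a
    fully deterministic paired-repertoire and clinical-cohort simulator
    with ground-truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
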