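Package: phagepan
Title: Comparative Genomics and Pangenome-Based Taxonomy for Phage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for delineating bacteriophage taxa from
    whole genomes: VIRIDIC-style pairwise intergenomic nucleotide similarity,
    greedy centroid protein clustering at configurable identity/coverage
    thresholds, pangenome presence/absence analysis with core, accessory and
    clade-signature cluster identification, shared-cluster (Jaccard)
    similarity statistics, threshold-based species/genus rank demarcation,
    and a core-genome neighbor-joining phylogeny with cluster-resampling
    support and Robinson-Foulds congruence testing against single-marker
    trees. Includes a synthetic phage-community generator with known clade
    structure and gene-family repertoires so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
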