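Package: rhizonet
Title: Rhizosphere Fungal Community, Biomarker and Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for paired two-condition rhizosphere
    microbiome surveys: rarefaction, alpha diversity, Bray-Curtis ordination
    (PCoA) and the ANOSIM permutation test; two-class biomarker discovery by
    Kruskal-Wallis screening with a bootstrap linear-discriminant effect
    size; Spearman co-occurrence network construction with modularity-based
    module detection, within-module degree z-score and participation
    coefficient (Zi-Pi) node roles, and keystone taxon comparison; and
    environment-community association via VIF-screened canonical
    correspondence analysis, phylum-soil correlation matrices, and LMG
    relative-importance decomposition. Includes a seeded synthetic-data
    generator that plants known biomarkers, correlated OTU modules with hub
    nodes, and soil couplings so every stage can be verified against ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    randomForest
Config/testthat/edition: 3
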