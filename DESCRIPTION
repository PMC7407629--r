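Package: hcapca
Title: Hierarchical Clustering with Variance-Gated PCA for Untargeted Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Dereplication and prioritization of large microbial strain
    collections from untargeted LCMS feature tables. Samples are clustered by
    UPGMA on Euclidean or correlation distances, the dendrogram is partitioned
    recursively at its first branch point, and recursion stops when the summed
    explained variance of the first two principal components (SoV12) of a
    cluster's Pareto-scaled intensity submatrix reaches a user-set cutoff
    (default 25 percent). Terminal nodes carry full PCA models whose scores and
    loadings flag chemically unusual strains and the molecular features that
    drive them. Includes readers and writers for the four-file .dat bundle and
    MZmine-style aligned feature CSV exports, a planted-structure synthetic
    data generator, JSON/newick/TSV exports, a static report, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust
Config/testthat/edition: 3
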