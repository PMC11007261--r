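Package: phylosym
Title: Phylosymbiosis Testing for Host-Associated Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests for phylosymbiosis -- the pattern in which microbial
    community dissimilarity recapitulates host phylogeny -- in
    multi-population amplicon surveys. Provides rarefaction, alpha and
    beta diversity (Jaccard, Bray-Curtis, unweighted and weighted
    UniFrac), host covariate distance matrices (Kimura two-parameter
    with gamma rate heterogeneity, great-circle geography, Gower),
    permutation matrix statistics (Mantel, partial Mantel, multiple
    regression on distance matrices, PERMANOVA), a co-dendrogram
    Robinson-Foulds congruence test against randomized-tree nulls,
    subsample sensitivity analysis, co-occurrence network Zi-Pi
    keystone classification, and a paired host-tree plus microbiome
    community simulator for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
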