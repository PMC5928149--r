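Package: microcooc
Title: Compositional Co-Occurrence Network Inference for Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers bacteria-bacteria co-occurrence networks from compositional
    OTU count tables using SparCC-style log-ratio variance estimation with
    permutation pseudo p-values, builds signed interaction networks on a fixed
    node universe, computes a full suite of network descriptors (density, signed
    link counts and means, subnetworks, degree statistics) and classifies OTUs
    into ecological roles (competitor, cooperator, neutral, hub). Also provides
    the community-comparison toolkit used to evaluate recolonization outcomes:
    low-read OTU filtering, rarefaction, Chao1 alpha diversity, Bray-Curtis
    dissimilarity, principal coordinates analysis, PERMANOVA, and isolate
    fold-change estimation, together with a synthetic OTU-table generator with
    planted, positive-semidefinite-repaired basis correlation structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
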