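Package: synpop
Title: Simulation and Genomic Analysis of Synthetic Populations of
    Outcrossing Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying the genetic constitution and variance of
    synthetic (SYN) seed-multiplication generations of outcrossing crops
    such as intermediate wheatgrass. Provides a forward-in-time simulator
    of SYN advancement from a configurable number of founder parents with
    additive polygenic traits and no selection; generators for synthetic
    founder pools, GBS-like genotype matrices and multi-year phenotypes;
    marker and individual filtering with LD-kNN imputation of missing
    dosages; population-genetic characterization (Weir-Cockerham Fst,
    Nei's genetic distance, Shannon's diversity index, principal component
    structure, linkage-disequilibrium decay); and ridge-regression BLUP
    genomic prediction with REML variance components, k-fold
    cross-validation and Tukey HSD comparisons across generations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
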