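Package: phenoscape
Title: Phenotyping Mutant Mouse Embryos from Whole-Embryo Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical toolkit for phenotyping mutant mouse embryos against
    wild-type references in whole-embryo single-cell RNA-seq atlases. Implements
    per-cell k-nearest-neighbour enrichment scores (lochNESS) with permutation
    nulls and deviance screening, beta-binomial regression for cell-composition
    changes with Dirichlet-based power simulation, embryo and genotype
    neighbourhood similarity scores, k-nearest-neighbour developmental time
    scores with a delay test, reciprocal non-negative least-squares matching of
    cell trajectories between atlases, label transfer with assigned scores,
    quality-control filters and pseudobulk PCA staging, and synthetic cohort
    generators that emulate the data structure every stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    MASS,
    methods,
    dplyr,
    generics,
    tibble,
    rlang,
    ggplot2,
    pracma,
    stats,
    utils
Suggests:
    glmmTMB,
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
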