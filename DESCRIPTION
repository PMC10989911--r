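Package: pandec
Title: Strain-Level Decomposition of Pangenome Coverage Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the composition and gene content of coexisting
    bacterial strains from multi-sample metagenomic pangenome coverage
    profiles. A gene-family by sample abundance matrix is decomposed by
    sparse nonnegative matrix factorization into a binary gene-content
    matrix (gene families by strains) and a strain composition matrix
    (strains by samples), with automatic selection of the number of
    strains, density-based binarization of gene-content weights with
    per-gene confidence scores, benchmark metrics (Jensen-Shannon
    divergence, Matthews correlation coefficient, Jaccard distance,
    precision-recall curves), and a matrix-level synthetic mixture
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
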