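Package: plastinet
Title: Teams, Multistability and Phenotype Scoring in Gene Regulatory
    Networks of Cancer Cell Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Systems-level analysis of small signed gene regulatory
    networks driving epithelial-mesenchymal plasticity. Computes
    path-weighted influence matrices and detects mutually antagonistic
    "teams" of genes with an edge-shuffled randomization null; simulates
    random-circuit-perturbation (RACIPE-style) ensembles of shifted-Hill
    ordinary differential equation models to map multistability; scores
    steady states along epithelial-mesenchymal and stemness axes with
    Gaussian-mixture thresholds and conditional probabilities; and scores
    expression matrices with single-sample gene-set enrichment and a
    signed Kolmogorov-Smirnov epithelial-mesenchymal metric. Includes
    generators for team-structured synthetic expression data and toy
    topologies with known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    mclust,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    e1071,
    jsonlite
Config/testthat/edition: 3
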