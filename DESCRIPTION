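Package: omicsnmf
Title: Integrative Clustering of Multi-Omics Data by Joint Non-Negative
    Matrix Factorization
Version: 1.0.0
Authors@R:
    person("omicsnmf", "developers", email = "omicsnmf@example.org",
           role = c("aut", "cre"))
Description: Joint clustering of multiple non-negative omics matrices
    (expression, methylation, protein, copy number) measured on the same
    samples. A common basis matrix W and layer-specific coefficient matrices
    H^i are fitted by alternating non-negativity-constrained least squares
    with exact active-set solves, initialised by NNDSVD or uniform random
    starts. Cluster-number selection uses consensus-matrix statistics
    (silhouette width, cophenetic correlation, dispersion), the residual
    sum of squares elbow, and a cross-validated cluster prediction index.
    Includes external validation metrics (adjusted Rand index, purity,
    entropy), a synthetic multi-omics generator with known cluster
    structure, and a command-line interface for fitting, k-selection and
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
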