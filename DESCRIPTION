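Package: ncinet
Title: Gene Regulatory Network Inference with Simultaneous Community Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Infers sparse, stable linear gene regulatory networks from
    time-course expression data while simultaneously detecting community
    subnetworks (the NCI method).  Network estimation solves a weighted
    L1-penalised least-squares problem with a per-gene row-stability
    constraint, decomposed into independent convex quadratic programs.
    Community structure is estimated by a weighted robust-PCA decomposition
    ("Block PCA") solved with a three-operator splitting algorithm, and
    communities are read off the low-rank factor by sparse singular value
    decomposition.  Includes a synthetic benchmark generator for stable,
    sparse, community-structured networks and their simulated expression
    time courses, plus evaluation utilities (trichotomous sign accuracy,
    paired method benchmarks).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
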