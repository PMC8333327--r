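Package: zoopcurves
Title: Zooplankton Community Structure and Environmental Response-Curve
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Turns per-individual plankton-imaging exports (one record per
    imaged organism, with best-fit ellipse axes) into station-level
    community metrics: abundance in individuals per cubic metre and the
    median equivalent spherical diameter of nested taxonomic groups.
    Screens environmental covariates by Shapiro-Wilk normality and
    Spearman rank correlation, applies a collinearity filter that yields
    parallel temperature and oxygen covariate sets, fits penalized-spline
    additive models with term shrinkage and backward removal, and
    clusters the fitted covariate response curves by dynamic time warping
    distances with partitioning-around-medoids, cluster-validity indices
    and classical multidimensional scaling. A virtual-transect simulator
    with planted response shapes and full ground-truth bookkeeping
    supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    geosphere,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    mclust,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
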