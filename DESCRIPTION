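Package: neurogeom
Title: Information Geometry of Neural Population Manifolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates smooth statistical manifolds (a label-dependent mean
    surface plus a label-dependent noise covariance) from noisy neural
    population recordings, using a Gaussian-process mean fit combined with
    kernel regression of residual outer products (GKR), and a
    normality-free resampling variant (GKR-S).  On top of the fitted
    manifold it computes information-geometric quantities (tangent frames,
    Riemannian metric, lattice area, linear Fisher information, total and
    tangent-projected noise), spatial coding accuracy of local linear
    classifiers together with its Fisher-information upper bound, Bayesian
    linear ensemble averaging for metric-versus-speed trend inference, and
    Vietoris-Rips persistent-homology barcodes with shuffle-calibrated
    Betti numbers.  Includes synthetic generators (ring and bump tuning
    models with structured noise, independent Poisson speed-gain grid
    cells, a two-neuron correlation toy), reference estimators (label-bin
    averaging, Ledoit-Wolf shrinkage), and spike-train preprocessing
    (rate estimation, rate maps, gridness, speed filtering,
    speed-balanced resampling, normality scanning).
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
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
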