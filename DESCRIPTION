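Package: DomainScape
Title: Conformational Landscape Analysis of Multidomain Proteins from
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters molecular dynamics trajectories of large multidomain
    proteins into discrete conformational states. Frames are featurized as
    pairwise distances between strided C-alpha atoms, reduced by principal
    component analysis to the smallest dimension explaining a variance
    threshold, and clustered with full-covariance Gaussian mixture models;
    the cluster count is assessed with the elbow method (BIC curvature) and
    silhouette analysis, and representative frames closest to cluster
    centers are extracted. Companion geometry tools superpose frames on a
    rigid core, compute per-domain and internal (rigid-body-removed) RMSD
    against initial or iteratively averaged references, measure minimum
    interdomain C-alpha distances, classify open versus closed-contact
    conformations by a distance threshold, and detect interdomain salt
    bridges and hydrophobic contacts. A synthetic rigid-body ensemble
    generator with Markov state switching provides trajectories with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    cluster,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
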