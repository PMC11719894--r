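#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib DomainScape, .registration = TRUE
NULL

#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @export
setGeneric("identifier", function(x) standardGeneric("identifier"))

#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("runId", function(x) standardGeneric("runId"))

#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @export
setGeneric("systemType", function(x) standardGeneric("systemType"))

#' @export
setGeneric("domainNames", function(x) standardGeneric("domainNames"))

#' @export
setGeneric("domainRange", function(x, name) standardGeneric("domainRange"))

#' @export
setGeneric("domainResidues", function(x, name) standardGeneric("domainResidues"))

#' @export
setGeneric("residueDomains", function(x, residues) standardGeneric("residueDomains"))

#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))

#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @export
setGeneric("ensembleSpec", function(x) standardGeneric("ensembleSpec"))

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @export
setGeneric("pairIndex", function(x) standardGeneric("pairIndex"))

#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))

#' @export
setGeneric("featureAtoms", function(x) standardGeneric("featureAtoms"))

#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))

#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @export
setGeneric("gmmWeights", function(x) standardGeneric("gmmWeights"))

#' @export
setGeneric("gmmMeans", function(x) standardGeneric("gmmMeans"))

#' @export
setGeneric("gmmCovariances", function(x) standardGeneric("gmmCovariances"))

#' @export
setGeneric("logLikTrace", function(x) standardGeneric("logLikTrace"))

#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' @export
setGeneric("elbowK", function(x) standardGeneric("elbowK"))

#' @export
setGeneric("bestSilhouetteK", function(x) standardGeneric("bestSilhouetteK"))

#' @export
setGeneric("secondBestSilhouetteK", function(x) standardGeneric("secondBestSilhouetteK"))

#' @export
setGeneric("selectedModel", function(x, K) standardGeneric("selectedModel"))

#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @export
setGeneric("seriesMean", function(x) standardGeneric("seriesMean"))

#' @export
setGeneric("seriesSD", function(x) standardGeneric("seriesSD"))
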