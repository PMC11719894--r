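## PCA on the distance-feature matrix with a smallest-component-count
## selection rule at a variance-explained threshold.

#' Fit a PCA model on a feature matrix
#'
#' Columns are centered by their means and the covariance (1/(n-1)
#' normalization) is eigendecomposed via the singular-value route of
#' [stats::prcomp]. Component signs are fixed by making the
#' largest-magnitude loading of every component positive, so serialized
#' models are reproducible across platforms.
#'
#' @param features a [DistanceFeatures-class] or a plain frames x D matrix.
#' @return A [PCAModel-class].
#' @export
fitPCA <- function(features) {
  X <- if (is(features, "DistanceFeatures")) featureValues(features)
       else as.matrix(features)
  if (nrow(X) < 2L) stop("at least 2 frames required")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  L <- p$rotation
  for (k in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, k])), k] < 0) L[, k] <- -L[, k]
  }
  ev <- unname(p$sdev^2)
  dimnames(L) <- NULL
  new("PCAModel", center = unname(p$center), loadings = L,
      eigenvalues = ev, totalVariance = sum(ev))
}

#' Smallest component count reaching a variance threshold
#'
#' @param model a [PCAModel-class].
#' @param threshold variance-explained threshold in (0, 1]; default 0.80.
#' @return smallest m with cumulative explained-variance ratio >= threshold.
#' @export
nComponentsForThreshold <- function(model, threshold = 0.80) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  cum <- cumsum(explainedVariance(model))
  m <- which(cum >= threshold - 1e-12)[1]
  if (is.na(m)) m <- length(cum)  # numerical guard; cum reaches 1 by trace
  as.integer(m)
}

#' Project frames onto the leading components
#'
#' `scores = (values - center) %*% loadings[, 1:m]`. When projecting a
#' [DistanceFeatures-class], frame metadata is carried into the result.
#'
#' @param model a [PCAModel-class].
#' @param features a [DistanceFeatures-class] or frames x D matrix.
#' @param m retained dimension count (<= fitted components).
#' @return A [ReducedSpace-class].
#' @export
projectScores <- function(model, features, m) {
  X <- if (is(features, "DistanceFeatures")) featureValues(features)
       else as.matrix(features)
  if (ncol(X) != length(model@center))
    stop("feature dimension does not match the model")
  if (m < 1L || m > ncol(model@loadings))
    stop("m must lie in 1..", ncol(model@loadings))
  S <- sweep(X, 2, model@center) %*% model@loadings[, seq_len(m), drop = FALSE]
  fm <- if (is(features, "DistanceFeatures")) frameMeta(features)
        else S4Vectors::DataFrame(run = rep("run", nrow(X)),
                                  condition = rep("all", nrow(X)),
                                  frame = seq_len(nrow(X)))
  new("ReducedSpace", scores = unname(S), frameMeta = fm)
}

#' Serialize / load a PCA model as a JSON manifest
#'
#' Plain-text persistence of center, loadings and eigenvalues.
#'
#' @param model a [PCAModel-class].
#' @param path JSON file path.
#' @return `path` (write) or a [PCAModel-class] (read).
#' @export
writePCAModel <- function(model, path) {
  jsonlite::write_json(list(center = model@center,
                            loadings = model@loadings,
                            eigenvalues = model@eigenvalues,
                            totalVariance = model@totalVariance),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePCAModel
#' @export
readPCAModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PCAModel", center = as.numeric(o$center),
      loadings = as.matrix(o$loadings),
      eigenvalues = as.numeric(o$eigenvalues),
      totalVariance = as.numeric(o$totalVariance))
}
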