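## Distance featurization: strided CA picking and the frames x pairwise
## CA-CA distance matrix that downstream PCA/clustering consume.

#' DistanceFeatures: frames x pairwise-distance feature matrix
#'
#' Stored as a [SummarizedExperiment::SummarizedExperiment] with one assay
#' `"distances"` (features in rows, frames in columns), `rowData` columns
#' `i`/`j` giving the topology atom indices of each pair (i < j,
#' lexicographic order), and `colData` columns `run`, `condition`, `frame`.
#' [featureValues()] returns the frames x D orientation used by the
#' statistics layer.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("DistanceFeatures",
         contains = "SummarizedExperiment")

#' @describeIn DistanceFeatures frames x D distance matrix (Angstrom)
#' @param x a `DistanceFeatures`
#' @export
setMethod("featureValues", "DistanceFeatures", function(x)
  t(SummarizedExperiment::assay(x, "distances")))

#' @describeIn DistanceFeatures data.frame of atom-index pairs (i < j)
#'   defining the feature columns
#' @export
setMethod("pairIndex", "DistanceFeatures", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @describeIn DistanceFeatures per-frame metadata (run, condition, frame)
#' @export
setMethod("frameMeta", "DistanceFeatures", function(x)
  SummarizedExperiment::colData(x))

#' @describeIn DistanceFeatures ordered CA atom indices used as features
#' @export
setMethod("featureAtoms", "DistanceFeatures", function(x)
  S4Vectors::metadata(x)$featureAtoms)

#' @describeIn DistanceFeatures number of frames
#' @export
setMethod("nFrames", "DistanceFeatures", function(x) ncol(x))

#' Pick strided CA feature atoms
#'
#' Counts positions among CA-bearing residues starting at the first: the
#' CA atoms of positions 1, 1+stride, 1+2*stride, ... are selected. On a
#' 1275-residue chain a stride of 25 yields 51 atoms.
#'
#' @param structure [ProteinStructure-class] or [MDTrajectory-class].
#' @param stride positive integer picking stride (default 25).
#' @return strictly increasing atom indices into the structure.
#' @export
pickFeatureAtoms <- function(structure, stride = 25L) {
  if (stride < 1) stop("stride must be >= 1")
  caIdx <- selectAtoms(structure, atomName = "CA")
  if (length(caIdx) == 0L) stop("structure has no CA atoms")
  caIdx[seq(1L, length(caIdx), by = stride)]
}

#' Number of pairwise-distance features for n atoms
#'
#' `n (n - 1) / 2`: 51 atoms give 1275 features; all 1275 CA atoms of the
#' full-length chain would give 812,175.
#'
#' @param nAtoms atom count (>= 0).
#' @return non-negative integer.
#' @export
featureCount <- function(nAtoms) {
  stopifnot(nAtoms >= 0)
  as.integer(nAtoms * (nAtoms - 1) / 2)
}

#' Pairwise CA-CA distance features over pooled trajectories
#'
#' Rows are the concatenation of all runs' frames in input order (runs of
#' one system type are pooled for the analysis); column j holds the
#' Euclidean distance between atom pair `pairIndex(x)[j, ]` in every frame.
#' Pairs are ordered lexicographically in (i, j) with i < j.
#'
#' @param trajs an [MDTrajectory-class], a list of them sharing one
#'   topology, or a [SyntheticEnsemble-class].
#' @param atomIndices feature atom indices (e.g. from [pickFeatureAtoms()]).
#' @return A [DistanceFeatures-class].
#' @export
distanceFeatures <- function(trajs, atomIndices) {
  if (is(trajs, "SyntheticEnsemble")) trajs <- trajectories(trajs)
  if (is(trajs, "MDTrajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  na <- nAtoms(trajs[[1]])
  ref <- atomData(trajs[[1]])
  for (tr in trajs) {
    if (nAtoms(tr) != na || !identical(atomData(tr), ref))
      stop("all trajectories must share one topology")
  }
  if (any(atomIndices < 1L | atomIndices > na))
    stop("atom index out of range")
  n <- length(atomIndices)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  D <- featureCount(n)
  blocks <- list()
  meta <- list()
  for (tr in trajs) {
    nf <- nFrames(tr)
    vals <- matrix(NA_real_, nrow = nf, ncol = D)
    for (f in seq_len(nf)) {
      X <- coords(tr, frame = f)[atomIndices, , drop = FALSE]
      vals[f, ] <- stats::dist(X)  # dist() order == lexicographic (i, j)
    }
    blocks[[length(blocks) + 1L]] <- vals
    meta[[length(meta) + 1L]] <- S4Vectors::DataFrame(
      run = rep(runId(tr), nf), condition = rep(condition(tr), nf),
      frame = seq_len(nf))
  }
  values <- do.call(rbind, blocks)
  cd <- do.call(rbind, meta)
  rd <- S4Vectors::DataFrame(i = atomIndices[pairs[, 1]],
                             j = atomIndices[pairs[, 2]])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(distances = t(values)), rowData = rd, colData = cd,
    metadata = list(featureAtoms = atomIndices))
  new("DistanceFeatures", se)
}

#' Write a feature matrix with its sidecar tables
#'
#' The values go to a CSV matrix (frames x D), atom pairs and frame
#' metadata to sidecar CSVs.
#'
#' @param features a [DistanceFeatures-class].
#' @param prefix output path prefix; writes `<prefix>_values.csv`,
#'   `<prefix>_pairs.csv`, `<prefix>_frames.csv`.
#' @return `prefix`, invisibly.
#' @export
writeFeatures <- function(features, prefix) {
  utils::write.csv(featureValues(features),
                   paste0(prefix, "_values.csv"), row.names = FALSE)
  utils::write.csv(pairIndex(features),
                   paste0(prefix, "_pairs.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(frameMeta(features)),
                   paste0(prefix, "_frames.csv"), row.names = FALSE)
  invisible(prefix)
}
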