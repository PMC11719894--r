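#' @importFrom S4Vectors DataFrame metadata
#' @importFrom IRanges IRanges start end width
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom S4Vectors DataFrame
NULL

## ---------------------------------------------------------------------------
## Structures and trajectories
## ---------------------------------------------------------------------------

#' ProteinStructure: one conformation of a protein
#'
#' Holds an ordered atom table (1-based residue index, 3-letter residue name,
#' atom name) and an n x 3 coordinate matrix in Angstrom.
#'
#' @slot atoms data.frame with columns `residue_index`, `residue_name`,
#'   `atom_name`, one row per atom, in file/chain order.
#' @slot coords numeric matrix, n x 3, Angstrom.
#' @slot identifier single string naming the structure.
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", coords = "matrix",
                 identifier = "character"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  x <- object@coords
  msg <- character()
  need <- c("residue_index", "residue_name", "atom_name")
  if (!all(need %in% names(a)))
    msg <- c(msg, "atoms must have columns residue_index, residue_name, atom_name")
  if (nrow(a) != nrow(x))
    msg <- c(msg, "atom table and coordinate matrix row counts differ")
  if (ncol(x) != 3L)
    msg <- c(msg, "coords must have 3 columns")
  if (nrow(x) > 0 && !all(is.finite(x)))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) return(msg)
  if (nrow(a) > 0) {
    ri <- a$residue_index
    if (any(ri < 1L)) msg <- c(msg, "residue indices must be >= 1")
    if (is.unsorted(ri)) msg <- c(msg, "residue indices must be non-decreasing")
    ca <- ri[a$atom_name == "CA"]
    if (anyDuplicated(ca))
      msg <- c(msg, "at most one CA atom per residue index")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinStructure
#'
#' @param atoms data.frame with `residue_index`, `residue_name`, `atom_name`.
#' @param coords n x 3 numeric matrix (Angstrom).
#' @param identifier string label.
#' @return A [ProteinStructure-class] object.
#' @export
ProteinStructure <- function(atoms, coords, identifier = "structure") {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  storage.mode(coords) <- "double"
  atoms <- as.data.frame(atoms)
  atoms$residue_index <- as.integer(atoms$residue_index)
  rownames(atoms) <- NULL
  new("ProteinStructure", atoms = atoms, coords = coords,
      identifier = as.character(identifier))
}

#' @describeIn ProteinStructure coordinate matrix (n x 3, Angstrom)
#' @param x,object a `ProteinStructure`
#' @export
setMethod("coords", "ProteinStructure", function(x, ...) x@coords)

#' @describeIn ProteinStructure atom table
#' @export
setMethod("atomData", "ProteinStructure", function(x) x@atoms)

#' @describeIn ProteinStructure structure identifier
#' @export
setMethod("identifier", "ProteinStructure", function(x) x@identifier)

#' @describeIn ProteinStructure number of atoms
#' @export
setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@coords))

setMethod("show", "ProteinStructure", function(object) {
  cat("ProteinStructure '", object@identifier, "': ",
      nAtoms(object), " atoms, residues ",
      if (nAtoms(object)) min(object@atoms$residue_index) else NA, "-",
      if (nAtoms(object)) max(object@atoms$residue_index) else NA, "\n", sep = "")
})

#' MDTrajectory: ordered frames sharing one topology
#'
#' @slot topology a [ProteinStructure-class]; atom order defines columns.
#' @slot coords numeric array, frames x atoms x 3, Angstrom.
#' @slot runId run label.
#' @slot condition condition label (e.g. apo, RNA, DNA, ternary).
#' @slot systemType starting-model label (open, closed, or custom).
#' @export
setClass("MDTrajectory",
  representation(topology = "ProteinStructure", coords = "array",
                 runId = "character", condition = "character",
                 systemType = "character"))

setValidity("MDTrajectory", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be a frames x atoms x 3 array")
  else {
    if (d[1] < 1L) msg <- c(msg, "at least one frame required")
    if (d[2] != nAtoms(object@topology))
      msg <- c(msg, "atom count does not match topology")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "all coordinates must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an MDTrajectory
#'
#' @param topology [ProteinStructure-class] shared by all frames.
#' @param coords frames x atoms x 3 array (Angstrom).
#' @param runId,condition,systemType metadata labels.
#' @return An [MDTrajectory-class].
#' @export
MDTrajectory <- function(topology, coords, runId = "run",
                         condition = "apo", systemType = "custom") {
  dimnames(coords) <- NULL
  new("MDTrajectory", topology = topology, coords = coords,
      runId = as.character(runId), condition = as.character(condition),
      systemType = as.character(systemType))
}

#' @describeIn MDTrajectory coordinates; full array, or one frame's n x 3
#'   matrix when `frame` is given
#' @param x,object an `MDTrajectory`
#' @param frame optional frame number
#' @export
setMethod("coords", "MDTrajectory", function(x, frame = NULL, ...) {
  if (is.null(frame)) return(x@coords)
  m <- x@coords[frame, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
})

#' @describeIn MDTrajectory shared topology
#' @export
setMethod("atomData", "MDTrajectory", function(x) x@topology@atoms)

#' @describeIn MDTrajectory number of frames
#' @export
setMethod("nFrames", "MDTrajectory", function(x) dim(x@coords)[1])

#' @describeIn MDTrajectory number of atoms
#' @export
setMethod("nAtoms", "MDTrajectory", function(x) dim(x@coords)[2])

#' @describeIn MDTrajectory run label
#' @export
setMethod("runId", "MDTrajectory", function(x) x@runId)

#' @describeIn MDTrajectory condition label
#' @export
setMethod("condition", "MDTrajectory", function(x) x@condition)

#' @describeIn MDTrajectory starting-model label
#' @export
setMethod("systemType", "MDTrajectory", function(x) x@systemType)

#' Topology of a trajectory
#' @param x an [MDTrajectory-class]
#' @return the shared [ProteinStructure-class]
#' @export
topology <- function(x) x@topology

setMethod("show", "MDTrajectory", function(object) {
  cat("MDTrajectory '", object@runId, "' (", object@condition, ", ",
      object@systemType, "): ", nFrames(object), " frames x ",
      nAtoms(object), " atoms\n", sep = "")
})

## ---------------------------------------------------------------------------
## Domain definitions
## ---------------------------------------------------------------------------

#' DomainMap: named residue intervals (1-based, inclusive)
#'
#' Intervals may overlap (the ORF2p wrist/CTD share residue 1061 as printed
#' in the source structure annotation); a residue outside every interval has
#' no domain and lookups for it fail explicitly. The composite "FPT"
#' (fingers + palm + thumb rigid core) is derived, not stored.
#'
#' @slot ranges named [IRanges::IRanges] of domain intervals.
#' @export
setClass("DomainMap", representation(ranges = "IRanges"))

setValidity("DomainMap", function(object) {
  r <- object@ranges
  msg <- character()
  if (is.null(names(r)) || any(names(r) == "") || anyDuplicated(names(r)))
    msg <- c(msg, "domains must have unique non-empty names")
  if (any(IRanges::width(r) < 1L))
    msg <- c(msg, "interval start must be <= end")
  if ("FPT" %in% names(r))
    msg <- c(msg, "'FPT' is reserved for the derived fingers+palm+thumb composite")
  if (length(msg)) msg else TRUE
})

#' Construct a DomainMap
#'
#' @param intervals named list of `c(start, end)` residue intervals
#'   (1-based, inclusive).
#' @return A [DomainMap-class].
#' @examples
#' DomainMap(list(A = c(1, 10), B = c(11, 20)))
#' @export
DomainMap <- function(intervals) {
  if (!length(intervals)) stop("at least one domain interval required")
  st <- vapply(intervals, function(v) as.integer(v[1]), integer(1))
  en <- vapply(intervals, function(v) as.integer(v[2]), integer(1))
  new("DomainMap",
      ranges = IRanges::IRanges(start = st, end = en,
                                names = names(intervals)))
}

#' @describeIn DomainMap domain names (excluding the derived FPT composite)
#' @param x,object a `DomainMap`
#' @export
setMethod("domainNames", "DomainMap", function(x) names(x@ranges))

#' @describeIn DomainMap `c(start, end)` of one domain; `"FPT"` is rejected
#'   (use [domainResidues()] for composites)
#' @param name domain name
#' @export
setMethod("domainRange", "DomainMap", function(x, name) {
  i <- match(name, names(x@ranges))
  if (is.na(i)) stop("unknown domain: ", name)
  c(IRanges::start(x@ranges)[i], IRanges::end(x@ranges)[i])
})

#' @describeIn DomainMap residue indices of a domain; `"FPT"` expands to the
#'   fingers + palm + thumb union when those domains exist
#' @export
setMethod("domainResidues", "DomainMap", function(x, name) {
  if (identical(name, "FPT")) {
    parts <- c("fingers", "palm", "thumb")
    if (!all(parts %in% names(x@ranges)))
      stop("FPT composite requires fingers, palm and thumb domains")
    return(sort(unique(unlist(lapply(parts, function(p) {
      r <- domainRange(x, p); seq.int(r[1], r[2])
    })))))
  }
  r <- domainRange(x, name)
  seq.int(r[1], r[2])
})

#' @describeIn DomainMap domain membership per residue; errors when any
#'   queried residue lies outside every interval
#' @param residues integer vector of residue indices
#' @export
setMethod("residueDomains", "DomainMap", function(x, residues) {
  st <- IRanges::start(x@ranges); en <- IRanges::end(x@ranges)
  out <- lapply(residues, function(r) names(x@ranges)[st <= r & r <= en])
  bad <- residues[lengths(out) == 0L]
  if (length(bad))
    stop("residue(s) outside all domain intervals: ",
         paste(utils::head(bad, 5), collapse = ", "))
  names(out) <- as.character(residues)
  out
})

setMethod("show", "DomainMap", function(object) {
  cat("DomainMap with", length(object@ranges), "domains:\n")
  df <- data.frame(domain = names(object@ranges),
                   start = IRanges::start(object@ranges),
                   end = IRanges::end(object@ranges))
  print(df, row.names = FALSE)
})

## ---------------------------------------------------------------------------
## Synthetic-ensemble specification
## ---------------------------------------------------------------------------

#' StateSpec: one conformational basin of the synthetic generator
#'
#' A rigid transform per domain (axis-angle rotation about the domain
#' centroid, then a translation), plus per-domain isotropic Gaussian jitter.
#' Domains absent from either list get the identity transform / zero jitter.
#'
#' @slot transforms named list; each element `list(angle=, axis=, translation=)`
#'   with angle in radians, axis a 3-vector, translation a 3-vector (Angstrom).
#' @slot jitter named numeric, per-domain jitter sigma (Angstrom).
#' @export
setClass("StateSpec",
  representation(transforms = "list", jitter = "numeric"))

setValidity("StateSpec", function(object) {
  msg <- character()
  for (nm in names(object@transforms)) {
    tr <- object@transforms[[nm]]
    if (!all(c("angle", "axis", "translation") %in% names(tr)))
      msg <- c(msg, sprintf("transform '%s' needs angle, axis, translation", nm))
    else if (tr$angle != 0 && sqrt(sum(tr$axis^2)) == 0)
      msg <- c(msg, sprintf("transform '%s': rotation axis must be non-zero", nm))
  }
  if (length(object@jitter) && any(object@jitter < 0))
    msg <- c(msg, "jitter sigmas must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a StateSpec
#' @param transforms named list of `list(angle=, axis=, translation=)`.
#' @param jitter named numeric vector of per-domain sigmas (Angstrom).
#' @return A [StateSpec-class].
#' @export
StateSpec <- function(transforms = list(), jitter = numeric()) {
  new("StateSpec", transforms = transforms, jitter = jitter)
}

#' Rigid domain transform helper
#' @param angle rotation angle, radians.
#' @param axis rotation axis (3-vector, need not be unit).
#' @param translation translation, Angstrom (3-vector).
#' @return list usable in [StateSpec()].
#' @export
domainTransform <- function(angle = 0, axis = c(0, 0, 1),
                            translation = c(0, 0, 0)) {
  list(angle = angle, axis = axis, translation = translation)
}

#' EnsembleSpec: full synthetic-ensemble description
#'
#' @slot topology reference [ProteinStructure-class] (CA-only chain).
#' @slot domainMap [DomainMap-class] over the topology's residues.
#' @slot states list of [StateSpec-class], one per conformational basin.
#' @slot transitionMatrix K x K Markov transition matrix (rows sum to 1).
#' @slot framesPerRun frames in each run.
#' @slot runsPerCondition named integer, runs per condition label.
#' @slot initialDistribution named list, condition -> initial state
#'   probability K-vector.
#' @slot systemType label propagated to generated trajectories.
#' @slot seed base RNG seed; run r uses seed + r.
#' @export
setClass("EnsembleSpec",
  representation(topology = "ProteinStructure", domainMap = "DomainMap",
                 states = "list", transitionMatrix = "matrix",
                 framesPerRun = "integer", runsPerCondition = "integer",
                 initialDistribution = "list", systemType = "character",
                 seed = "integer"))

setValidity("EnsembleSpec", function(object) {
  K <- length(object@states)
  P <- object@transitionMatrix
  msg <- character()
  if (K < 1L) msg <- c(msg, "at least one state required")
  if (!all(dim(P) == c(K, K)))
    msg <- c(msg, "transition matrix must be K x K")
  else if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    msg <- c(msg, "transition matrix rows must sum to 1 (within 1e-12)")
  for (s in object@states)
    for (nm in names(s@transforms))
      if (!nm %in% domainNames(object@domainMap))
        msg <- c(msg, sprintf("transform references unknown domain '%s'", nm))
  if (object@framesPerRun < 1L) msg <- c(msg, "framesPerRun must be >= 1")
  for (cn in names(object@runsPerCondition)) {
    p0 <- object@initialDistribution[[cn]]
    if (is.null(p0) || length(p0) != K || abs(sum(p0) - 1) > 1e-8)
      msg <- c(msg, sprintf("initial distribution for '%s' must be a K-vector summing to 1", cn))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EnsembleSpec
#'
#' @param topology,domainMap,states,transitionMatrix,framesPerRun see slots.
#' @param runsPerCondition named integer vector (condition -> number of runs).
#' @param initialDistribution named list (condition -> K-vector) or NULL for
#'   the uniform distribution in every condition.
#' @param systemType trajectory label (default "custom").
#' @param seed base seed.
#' @return An [EnsembleSpec-class].
#' @export
EnsembleSpec <- function(topology, domainMap, states, transitionMatrix,
                         framesPerRun = 400L,
                         runsPerCondition = c(apo = 3L),
                         initialDistribution = NULL,
                         systemType = "custom", seed = 1L) {
  K <- length(states)
  if (is.null(initialDistribution))
    initialDistribution <- stats::setNames(
      rep(list(rep(1 / K, K)), length(runsPerCondition)),
      names(runsPerCondition))
  new("EnsembleSpec", topology = topology, domainMap = domainMap,
      states = states, transitionMatrix = transitionMatrix,
      framesPerRun = as.integer(framesPerRun),
      runsPerCondition = stats::setNames(as.integer(runsPerCondition),
                                         names(runsPerCondition)),
      initialDistribution = initialDistribution,
      systemType = as.character(systemType), seed = as.integer(seed))
}

setMethod("show", "EnsembleSpec", function(object) {
  cat("EnsembleSpec:", length(object@states), "states,",
      sum(object@runsPerCondition), "runs x", object@framesPerRun,
      "frames,", nAtoms(object@topology), "atoms\n")
  cat("  conditions:", paste(names(object@runsPerCondition), collapse = ", "),
      " seed:", object@seed, "\n")
})

#' SyntheticEnsemble: generated runs with planted ground truth
#'
#' @slot trajectories list of [MDTrajectory-class], one per run.
#' @slot labels list of integer vectors (1-based planted state per frame),
#'   parallel to `trajectories`.
#' @slot spec the [EnsembleSpec-class] used.
#' @export
setClass("SyntheticEnsemble",
  representation(trajectories = "list", labels = "list",
                 spec = "EnsembleSpec"))

setValidity("SyntheticEnsemble", function(object) {
  K <- length(object@spec@states)
  msg <- character()
  if (length(object@trajectories) != length(object@labels))
    msg <- c(msg, "one label vector per trajectory required")
  for (i in seq_along(object@labels)) {
    l <- object@labels[[i]]
    if (any(l < 1L | l > K)) msg <- c(msg, "labels must lie in 1..K")
    if (length(l) != nFrames(object@trajectories[[i]]))
      msg <- c(msg, "label length must equal frame count")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticEnsemble list of generated trajectories
#' @param x,object a `SyntheticEnsemble`
#' @export
setMethod("trajectories", "SyntheticEnsemble", function(x) x@trajectories)

#' @describeIn SyntheticEnsemble planted per-frame state labels, pooled over
#'   runs in generation order (matches feature-matrix row order)
#' @export
setMethod("stateLabels", "SyntheticEnsemble",
          function(x) unlist(x@labels, use.names = FALSE))

#' @describeIn SyntheticEnsemble the generating spec
#' @export
setMethod("ensembleSpec", "SyntheticEnsemble", function(x) x@spec)

setMethod("show", "SyntheticEnsemble", function(object) {
  cat("SyntheticEnsemble:", length(object@trajectories), "runs,",
      length(stateLabels(object)), "frames,",
      length(object@spec@states), "planted states\n")
})

## ---------------------------------------------------------------------------
## PCA and reduced space
## ---------------------------------------------------------------------------

#' PCAModel: fitted principal component basis
#'
#' @slot center column means of the training features.
#' @slot loadings D x r orthonormal loading matrix, components in columns,
#'   ordered by decreasing eigenvalue; the largest-magnitude entry of each
#'   column is positive (sign convention).
#' @slot eigenvalues variances along components, descending.
#' @slot totalVariance total variance of the (centered) training data.
#' @export
setClass("PCAModel",
  representation(center = "numeric", loadings = "matrix",
                 eigenvalues = "numeric", totalVariance = "numeric"))

setValidity("PCAModel", function(object) {
  msg <- character()
  if (ncol(object@loadings) != length(object@eigenvalues))
    msg <- c(msg, "one eigenvalue per loading column required")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be sorted descending")
  if (any(object@eigenvalues < -1e-10))
    msg <- c(msg, "eigenvalues must be non-negative")
  G <- crossprod(object@loadings)
  if (max(abs(G - diag(ncol(G)))) > 1e-8)
    msg <- c(msg, "loadings must be orthonormal (within 1e-8)")
  if (length(msg)) msg else TRUE
})

#' @describeIn PCAModel loading matrix (components in columns)
#' @param x,object a `PCAModel`
#' @export
setMethod("loadings", "PCAModel", function(x) x@loadings)

#' @describeIn PCAModel component variances, descending
#' @export
setMethod("eigenvalues", "PCAModel", function(x) x@eigenvalues)

#' @describeIn PCAModel explained-variance ratios (eigenvalue / total variance)
#' @export
setMethod("explainedVariance", "PCAModel",
          function(x) x@eigenvalues / x@totalVariance)

setMethod("show", "PCAModel", function(object) {
  r <- explainedVariance(object)
  cat("PCAModel:", nrow(object@loadings), "features,",
      length(object@eigenvalues), "components\n")
  cat("  explained variance:",
      paste(sprintf("%.3f", utils::head(r, 5)), collapse = " "),
      if (length(r) > 5) "...\n" else "\n")
})

#' ReducedSpace: frames projected onto retained components
#'
#' @slot scores frames x m score matrix.
#' @slot frameMeta [S4Vectors::DataFrame] with `run`, `condition`, `frame`
#'   per row.
#' @export
setClass("ReducedSpace",
  representation(scores = "matrix", frameMeta = "DataFrame"))

setValidity("ReducedSpace", function(object) {
  msg <- character()
  if (ncol(object@scores) < 1L) msg <- c(msg, "at least one dimension required")
  if (nrow(object@frameMeta) != nrow(object@scores))
    msg <- c(msg, "frameMeta rows must match score rows")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReducedSpace score matrix (frames x m)
#' @param x,object a `ReducedSpace`
#' @export
setMethod("scores", "ReducedSpace", function(x) x@scores)

#' @describeIn ReducedSpace per-frame metadata
#' @export
setMethod("frameMeta", "ReducedSpace", function(x) x@frameMeta)

#' @describeIn ReducedSpace number of frames
#' @export
setMethod("nFrames", "ReducedSpace", function(x) nrow(x@scores))

setMethod("show", "ReducedSpace", function(object) {
  cat("ReducedSpace:", nrow(object@scores), "frames x",
      ncol(object@scores), "dimensions\n")
})

## ---------------------------------------------------------------------------
## Gaussian mixture clustering
## ---------------------------------------------------------------------------

#' GMMFit: fitted full-covariance Gaussian mixture
#'
#' @slot K number of components.
#' @slot weights mixing weights, sum to 1.
#' @slot means K x m component means.
#' @slot covariances m x m x K array of full covariance matrices.
#' @slot logLik converged log-likelihood of the best initialization.
#' @slot logLikTrace per-iteration log-likelihood of the best initialization
#'   (non-decreasing, an EM guarantee).
#' @slot seed RNG seed used.
#' @slot converged TRUE when the tolerance was reached before the
#'   iteration cap.
#' @export
setClass("GMMFit",
  representation(K = "integer", weights = "numeric", means = "matrix",
                 covariances = "array", logLik = "numeric",
                 logLikTrace = "numeric", seed = "integer",
                 converged = "logical"))

setValidity("GMMFit", function(object) {
  msg <- character()
  if (length(object@weights) != object@K)
    msg <- c(msg, "one weight per component required")
  if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-10)
    msg <- c(msg, "weights must be non-negative and sum to 1 (within 1e-10)")
  if (nrow(object@means) != object@K)
    msg <- c(msg, "one mean per component required")
  for (k in seq_len(object@K)) {
    ev <- eigen(object@covariances[, , k], symmetric = TRUE,
                only.values = TRUE)$values
    if (any(ev <= 0))
      msg <- c(msg, "covariances must be positive-definite")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GMMFit mixing weights
#' @param x,object a `GMMFit`
#' @export
setMethod("gmmWeights", "GMMFit", function(x) x@weights)

#' @describeIn GMMFit component means (K x m)
#' @export
setMethod("gmmMeans", "GMMFit", function(x) x@means)

#' @describeIn GMMFit covariance array (m x m x K)
#' @export
setMethod("gmmCovariances", "GMMFit", function(x) x@covariances)

#' @describeIn GMMFit per-iteration log-likelihood of the winning start
#' @export
setMethod("logLikTrace", "GMMFit", function(x) x@logLikTrace)

#' @describeIn GMMFit converged log-likelihood
#' @importFrom stats logLik
#' @export
setMethod("logLik", "GMMFit", function(object, ...) object@logLik)

setMethod("show", "GMMFit", function(object) {
  cat("GMMFit: K =", object@K, " logLik =", format(object@logLik),
      if (object@converged) "(converged)\n" else "(iteration cap)\n")
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "), "\n")
})

#' ModelSelectionReport: elbow and silhouette scan over K
#'
#' Nothing is auto-selected: the elbow K and the silhouette ranking are both
#' reported and the caller weighs them, since the two heuristics can
#' legitimately disagree.
#'
#' @slot table data.frame with columns K, negLogLik, BIC, silhouette.
#' @slot elbowK the largest scanned K whose score improvement is still a
#'   material fraction of the curve's total drop (where the scree curve
#'   flattens); equals the smallest scanned K when the curve never drops
#'   materially.
#' @slot bestSilhouetteK,secondBestSilhouetteK silhouette ranking.
#' @slot models list of [GMMFit-class], one per scanned K.
#' @export
setClass("ModelSelectionReport",
  representation(table = "data.frame", elbowK = "integer",
                 bestSilhouetteK = "integer",
                 secondBestSilhouetteK = "integer", models = "list"))

setValidity("ModelSelectionReport", function(object) {
  s <- object@table$silhouette
  if (length(s) && any(s < -1 - 1e-9 | s > 1 + 1e-9, na.rm = TRUE))
    "silhouette scores must lie in [-1, 1]" else TRUE
})

#' @describeIn ModelSelectionReport per-K score table
#' @param x,object a `ModelSelectionReport`
#' @export
setMethod("selectionTable", "ModelSelectionReport", function(x) x@table)

#' @describeIn ModelSelectionReport elbow choice of K
#' @export
setMethod("elbowK", "ModelSelectionReport", function(x) x@elbowK)

#' @describeIn ModelSelectionReport K with the best mean silhouette
#' @export
setMethod("bestSilhouetteK", "ModelSelectionReport", function(x) x@bestSilhouetteK)

#' @describeIn ModelSelectionReport runner-up K by mean silhouette
#' @export
setMethod("secondBestSilhouetteK", "ModelSelectionReport",
          function(x) x@secondBestSilhouetteK)

#' @describeIn ModelSelectionReport retrieve the fitted mixture for one K
#' @param K which scanned cluster count
#' @export
setMethod("selectedModel", "ModelSelectionReport", function(x, K) {
  i <- match(K, x@table$K)
  if (is.na(i)) stop("K = ", K, " was not scanned")
  x@models[[i]]
})

setMethod("show", "ModelSelectionReport", function(object) {
  cat("ModelSelectionReport over K =",
      paste(range(object@table$K), collapse = ".."), "\n")
  print(object@table, row.names = FALSE, digits = 4)
  cat("  elbow K:", object@elbowK,
      " best silhouette K:", object@bestSilhouetteK,
      " second best:", object@secondBestSilhouetteK, "\n")
})

## ---------------------------------------------------------------------------
## Geometry results
## ---------------------------------------------------------------------------

#' SuperpositionResult: least-squares rigid fit
#'
#' The fit maps mobile coordinates onto the reference:
#' `aligned = mobile %*% t(rotation) + translation` (rows are points).
#'
#' @slot rotation proper 3 x 3 rotation matrix (det = +1).
#' @slot translation length-3 vector, Angstrom.
#' @slot rmsd RMSD over the fitted atoms after superposition, Angstrom.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  msg <- character()
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    msg <- c(msg, "rotation must be orthonormal (within 1e-8)")
  if (det(R) < 0) msg <- c(msg, "reflections are excluded (det must be +1)")
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' RMSDSeries: per-frame RMSD for one domain
#'
#' @slot values per-frame RMSD, Angstrom.
#' @slot domain domain name.
#' @slot referenceKind "initial" or "average".
#' @export
setClass("RMSDSeries",
  representation(values = "numeric", domain = "character",
                 referenceKind = "character"))

setValidity("RMSDSeries", function(object) {
  if (length(object@values) && any(object@values < -1e-12))
    "RMSD values must be >= 0" else TRUE
})

#' @describeIn RMSDSeries per-frame values
#' @param x,object an `RMSDSeries`
#' @export
setMethod("seriesValues", "RMSDSeries", function(x) x@values)

#' @describeIn RMSDSeries mean over frames
#' @export
setMethod("seriesMean", "RMSDSeries", function(x) mean(x@values))

#' @describeIn RMSDSeries standard deviation over frames
#' @export
setMethod("seriesSD", "RMSDSeries", function(x) stats::sd(x@values))

setMethod("show", "RMSDSeries", function(object) {
  cat(sprintf("RMSDSeries [%s vs %s]: %d frames, mean %.2f (sd %.2f) A\n",
              object@domain, object@referenceKind, length(object@values),
              seriesMean(object), seriesSD(object)))
})

#' DistanceSeries: per-frame minimum interdomain CA-CA distance
#'
#' @slot values per-frame minimum distance, Angstrom.
#' @slot domains the two domain names.
#' @export
setClass("DistanceSeries",
  representation(values = "numeric", domains = "character"))

setValidity("DistanceSeries", function(object) {
  if (length(object@values) && any(object@values < 0))
    "distances must be >= 0" else TRUE
})

#' @describeIn DistanceSeries per-frame values
#' @param x,object a `DistanceSeries`
#' @export
setMethod("seriesValues", "DistanceSeries", function(x) x@values)

#' @describeIn DistanceSeries mean over frames
#' @export
setMethod("seriesMean", "DistanceSeries", function(x) mean(x@values))

#' @describeIn DistanceSeries standard deviation over frames
#' @export
setMethod("seriesSD", "DistanceSeries", function(x) stats::sd(x@values))

setMethod("show", "DistanceSeries", function(object) {
  cat(sprintf("DistanceSeries [%s-%s]: %d frames, min %.2f, mean %.2f A\n",
              object@domains[1], object@domains[2], length(object@values),
              min(object@values), seriesMean(object)))
})
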