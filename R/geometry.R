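## Rigid-core superposition, per-domain RMSD, minimum interdomain distances
## and the distance-threshold open/closed-contact classification.

#' Backbone atom indices of a residue set
#'
#' "Backbone" means N, CA, C where present; on CA-only data the CA atoms
#' alone are used.
#'
#' @param structure [ProteinStructure-class] or [MDTrajectory-class].
#' @param residues residue indices (NULL for all).
#' @return integer atom indices.
#' @export
backboneAtomIndices <- function(structure, residues = NULL) {
  if (is(structure, "MDTrajectory")) structure <- topology(structure)
  a <- atomData(structure)
  keep <- a$atom_name %in% c("N", "CA", "C")
  if (!any(keep)) keep <- a$atom_name == "CA"
  if (!is.null(residues)) keep <- keep & a$residue_index %in% residues
  which(keep)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation mapping `mobile` onto
#' `reference`, reflections excluded. Rows are points; optional weights
#' apply per point.
#'
#' @param mobile,reference n x 3 coordinate matrices (n >= 3).
#' @param weights optional non-negative per-point weights.
#' @return A [SuperpositionResult-class]; apply with
#'   [applySuperposition()].
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ")
  if (n < 3L) stop("at least 3 points required")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  mc <- colSums(mobile * w)
  rc <- colSums(reference * w)
  P <- sweep(mobile, 2, mc)
  Q <- sweep(reference, 2, rc)
  H <- crossprod(P * w, Q)  # 3 x 3 weighted covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    warning("(nearly) collinear point set; rotation is ill-determined")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(rc - R %*% mc)
  aligned <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((aligned - Q)^2)))
  new("SuperpositionResult", rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a fitted superposition to coordinates
#'
#' @param fit a [SuperpositionResult-class].
#' @param xyz n x 3 coordinates.
#' @return transformed n x 3 coordinates.
#' @export
applySuperposition <- function(fit, xyz) {
  sweep(as.matrix(xyz) %*% t(fit@rotation), 2, fit@translation, "+")
}

#' Superpose every frame on a rigid core
#'
#' The Kabsch fit is computed on the core atoms only and the resulting
#' rigid transform is applied to all atoms of the frame.
#'
#' @param trajectory an [MDTrajectory-class].
#' @param coreIndices atom indices of the alignment core (e.g. the
#'   fingers-palm-thumb backbone).
#' @param reference [ProteinStructure-class] to align onto, or an n x 3
#'   coordinate matrix; defaults to the trajectory's topology.
#' @return the aligned [MDTrajectory-class].
#' @export
superposeOnCore <- function(trajectory, coreIndices, reference = NULL) {
  refX <- if (is.null(reference)) coords(topology(trajectory))
          else if (is(reference, "ProteinStructure")) coords(reference)
          else as.matrix(reference)
  if (nrow(refX) != nAtoms(trajectory))
    stop("reference atom count does not match the trajectory")
  if (any(coreIndices < 1L | coreIndices > nAtoms(trajectory)))
    stop("core index out of range")
  refCore <- refX[coreIndices, , drop = FALSE]
  out <- trajectory@coords
  for (f in seq_len(nFrames(trajectory))) {
    X <- coords(trajectory, frame = f)
    fit <- kabsch(X[coreIndices, , drop = FALSE], refCore)
    out[f, , ] <- applySuperposition(fit, X)
  }
  methods::initialize(trajectory, coords = out)
}

#' Iterated average structure of an aligned trajectory
#'
#' Alternates {mean coordinates over frames; realign all frames on the core
#' to that mean} until the mean moves less than `tol` (RMS over atoms) or
#' `maxIter` is reached. The fixed point is reproducible across
#' implementations, unlike a single-pass mean.
#'
#' @param trajectory an [MDTrajectory-class] (typically already
#'   core-aligned; the iteration realigns internally regardless).
#' @param coreIndices core atom indices used for the realignment.
#' @param tol convergence tolerance on the mean coordinates, Angstrom
#'   (default 1e-4).
#' @param maxIter iteration cap (default 20).
#' @return A [ProteinStructure-class] with the converged mean coordinates;
#'   non-convergence warns and returns the last iterate.
#' @export
averageStructure <- function(trajectory, coreIndices, tol = 1e-4,
                             maxIter = 20L) {
  cur <- trajectory
  avg <- apply(cur@coords, c(2, 3), mean)
  for (it in seq_len(maxIter)) {
    cur <- superposeOnCore(cur, coreIndices, avg)
    newAvg <- apply(cur@coords, c(2, 3), mean)
    delta <- sqrt(mean(rowSums((newAvg - avg)^2)))
    avg <- newAvg
    if (delta < tol) {
      return(ProteinStructure(atomData(trajectory), avg,
                              identifier = "average"))
    }
  }
  warning("average structure did not converge within ", maxIter,
          " iterations (last change ", format(delta), " A)")
  ProteinStructure(atomData(trajectory), avg, identifier = "average")
}

#' Per-domain RMSD after core alignment
#'
#' RMSD of the domain's atoms against the reference, frame by frame, with
#' NO re-fitting on the domain: the alignment frame is whatever
#' superposition the trajectory already carries (normally the rigid core),
#' so the series mixes the domain's internal flexibility with its
#' rigid-body motion relative to the core.
#'
#' @param trajectory a core-aligned [MDTrajectory-class].
#' @param reference [ProteinStructure-class] or n x 3 matrix (full atom set).
#' @param domainIndices atom indices of the domain (non-empty).
#' @param domain domain name recorded in the result.
#' @param referenceKind "initial" or "average" (metadata).
#' @return An [RMSDSeries-class].
#' @export
domainRMSD <- function(trajectory, reference, domainIndices,
                       domain = "domain", referenceKind = "initial") {
  if (!length(domainIndices)) stop("empty domain selection")
  refX <- if (is(reference, "ProteinStructure")) coords(reference)
          else as.matrix(reference)
  refD <- refX[domainIndices, , drop = FALSE]
  vals <- vapply(seq_len(nFrames(trajectory)), function(f) {
    coordRMSD(coords(trajectory, frame = f)[domainIndices, , drop = FALSE],
              refD)
  }, numeric(1))
  new("RMSDSeries", values = vals, domain = domain,
      referenceKind = referenceKind)
}

#' Internal (rigid-body-removed) domain RMSD
#'
#' Each frame's domain is superposed onto the reference domain before the
#' RMSD is taken, eliminating the domain's own rotations and translations;
#' what remains measures internal flexibility only. Frame-wise this is
#' never larger than [domainRMSD()] (optimality of the least-squares fit).
#'
#' @param trajectory an [MDTrajectory-class] (alignment state irrelevant).
#' @param domainIndices atom indices of the domain (>= 3).
#' @param reference [ProteinStructure-class] or n x 3 matrix (full atom set).
#' @param domain,referenceKind metadata labels.
#' @return An [RMSDSeries-class].
#' @export
internalRMSD <- function(trajectory, domainIndices, reference,
                         domain = "domain", referenceKind = "initial") {
  if (length(domainIndices) < 3L) stop("at least 3 domain atoms required")
  refX <- if (is(reference, "ProteinStructure")) coords(reference)
          else as.matrix(reference)
  refD <- refX[domainIndices, , drop = FALSE]
  vals <- vapply(seq_len(nFrames(trajectory)), function(f) {
    kabsch(coords(trajectory, frame = f)[domainIndices, , drop = FALSE],
           refD)@rmsd
  }, numeric(1))
  new("RMSDSeries", values = vals, domain = domain,
      referenceKind = referenceKind)
}

#' Per-frame minimum interdomain CA-CA distance
#'
#' Minimum over all cross-domain atom pairs, per frame; symmetric in the
#' two selections, which must be disjoint.
#'
#' @param trajectory an [MDTrajectory-class].
#' @param indicesA,indicesB CA atom indices of the two domains.
#' @param domains length-2 character vector of domain names (metadata).
#' @return A [DistanceSeries-class].
#' @export
minInterdomainDistance <- function(trajectory, indicesA, indicesB,
                                   domains = c("A", "B")) {
  if (!length(indicesA) || !length(indicesB))
    stop("both domain selections must be non-empty")
  if (length(intersect(indicesA, indicesB)))
    stop("domain selections overlap")
  vals <- vapply(seq_len(nFrames(trajectory)), function(f) {
    X <- coords(trajectory, frame = f)
    min(crossDistances(X[indicesA, , drop = FALSE],
                       X[indicesB, , drop = FALSE]))
  }, numeric(1))
  new("DistanceSeries", values = vals, domains = domains)
}

#' Fraction of frames below a distance threshold
#'
#' Strict inequality ("less than").
#'
#' @param series a [DistanceSeries-class] or numeric vector.
#' @param threshold distance threshold, Angstrom (> 0); default 8.
#' @return fraction in `[0, 1]`.
#' @export
fractionBelow <- function(series, threshold = 8) {
  v <- if (is(series, "DistanceSeries")) seriesValues(series)
       else as.numeric(series)
  if (!length(v)) stop("empty distance series")
  if (threshold <= 0) stop("threshold must be > 0")
  mean(v < threshold)
}

#' Open / closed-contact classification by minimum interdomain distance
#'
#' A frame is "closed-contact" when the minimum CA-CA distance between the
#' two domains (conventionally CTD and tower) is strictly less than the
#' threshold, else "open". The default threshold is 8 Angstrom; 10 is the
#' customary looser alternative.
#'
#' @inheritParams fractionBelow
#' @return factor with levels `closed-contact`, `open`, one per frame.
#' @export
classifyOpenClosed <- function(series, threshold = 8) {
  v <- if (is(series, "DistanceSeries")) seriesValues(series)
       else as.numeric(series)
  if (threshold <= 0) stop("threshold must be > 0")
  factor(ifelse(v < threshold, "closed-contact", "open"),
         levels = c("closed-contact", "open"))
}

#' Export an RMSD or distance series as CSV
#'
#' @param series [RMSDSeries-class] or [DistanceSeries-class].
#' @param path output CSV.
#' @param meta optional per-frame metadata (run, condition) cbound in.
#' @return `path`, invisibly.
#' @export
writeSeries <- function(series, path, meta = NULL) {
  df <- data.frame(frame = seq_along(seriesValues(series)),
                   value = seriesValues(series))
  if (!is.null(meta)) df <- cbind(as.data.frame(meta), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
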