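## PDB / trajectory I/O. File parsing and writing are delegated to bio3d;
## this layer enforces the package's single-conformation vs trajectory
## contracts and the first-protein-chain convention.

bio3dToAtoms <- function(pdb, chain = NULL) {
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records found")
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!is.na(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records for chain ", chain)
  at
}

#' Read a single-conformation PDB structure
#'
#' Reads ATOM records of one chain (the first protein chain unless `chain`
#' is given). Multi-model files are rejected here; read them with
#' [readTrajectory()].
#'
#' @param path PDB file.
#' @param chain optional chain identifier.
#' @return A [ProteinStructure-class].
#' @export
readPDB <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = TRUE)),
                  error = function(e) stop("malformed PDB file: ",
                                           conditionMessage(e), call. = FALSE))
  if (nrow(pdb$xyz) > 1L)
    stop("multi-model file; use readTrajectory() for trajectories")
  at <- bio3dToAtoms(pdb, chain)
  ProteinStructure(
    atoms = data.frame(residue_index = at$resno, residue_name = at$resid,
                       atom_name = at$elety),
    coords = cbind(at$x, at$y, at$z),
    identifier = basename(path))
}

#' Write a structure as a PDB file
#'
#' @param structure a [ProteinStructure-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePDB <- function(structure, path) {
  a <- atomData(structure)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords(structure))),
                   resno = a$residue_index, resid = a$residue_name,
                   elety = a$atom_name)
  invisible(path)
}

#' Read a trajectory
#'
#' Multi-model PDB is the native format; DCD coordinate files are read with
#' a separate PDB topology. Atom counts between topology and frames must
#' agree.
#'
#' @param topologyPath PDB file defining the topology (for multi-model PDB
#'   input this may be the same file; its first model is the topology).
#' @param coordPath coordinate file; defaults to `topologyPath`.
#' @param format "pdb" (multi-model) or "dcd".
#' @param runId,condition,systemType metadata labels attached to the result.
#' @param chain optional chain identifier for the topology.
#' @return An [MDTrajectory-class].
#' @export
readTrajectory <- function(topologyPath, coordPath = topologyPath,
                           format = c("pdb", "dcd"),
                           runId = basename(coordPath), condition = "apo",
                           systemType = "custom", chain = NULL) {
  format <- match.arg(format)
  if (!file.exists(topologyPath)) stop("no such file: ", topologyPath)
  if (!file.exists(coordPath)) stop("no such file: ", coordPath)
  pdb <- suppressWarnings(bio3d::read.pdb(topologyPath, multi = TRUE))
  at <- bio3dToAtoms(pdb, chain)
  topo <- ProteinStructure(
    atoms = data.frame(residue_index = at$resno, residue_name = at$resid,
                       atom_name = at$elety),
    coords = cbind(at$x, at$y, at$z),
    identifier = basename(topologyPath))
  xyz <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(coordPath, multi = TRUE))$xyz
  } else {
    bio3d::read.dcd(coordPath, verbose = FALSE)
  }
  n <- ncol(xyz) / 3
  if (n != nAtoms(topo))
    stop("atom-count mismatch: topology has ", nAtoms(topo),
         " atoms, frames have ", n)
  arr <- array(NA_real_, dim = c(nrow(xyz), n, 3))
  for (d in 1:3) arr[, , d] <- xyz[, seq(d, by = 3, length.out = n), drop = FALSE]
  MDTrajectory(topo, arr, runId = runId, condition = condition,
               systemType = systemType)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param trajectory an [MDTrajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  a <- atomData(trajectory)
  nf <- nFrames(trajectory)
  na <- nAtoms(trajectory)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3 * na)
  for (d in 1:3) xyz[, seq(d, by = 3, length.out = na)] <- trajectory@coords[, , d]
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$residue_index,
                   resid = a$residue_name, elety = a$atom_name)
  invisible(path)
}

#' Select atoms by name and residue interval
#'
#' Residues missing the requested atom are simply absent from the result
#' (selection, not validation); use `requireNonEmpty` when downstream code
#' needs at least one atom.
#'
#' @param structure a [ProteinStructure-class] (or [MDTrajectory-class],
#'   whose topology is used).
#' @param atomName atom name to match (default "CA").
#' @param residueInterval `c(start, end)` 1-based inclusive, or NULL for all.
#' @param residues explicit residue index set (overrides `residueInterval`);
#'   used for composite domains.
#' @param requireNonEmpty error on an empty selection.
#' @return strictly increasing integer atom indices.
#' @export
selectAtoms <- function(structure, atomName = "CA", residueInterval = NULL,
                        residues = NULL, requireNonEmpty = FALSE) {
  if (is(structure, "MDTrajectory")) structure <- topology(structure)
  a <- atomData(structure)
  keep <- a$atom_name == atomName
  if (!is.null(residues)) {
    keep <- keep & a$residue_index %in% residues
  } else if (!is.null(residueInterval)) {
    if (length(residueInterval) != 2L || residueInterval[1] > residueInterval[2])
      stop("residueInterval must be c(start, end) with start <= end")
    keep <- keep & a$residue_index >= residueInterval[1] &
      a$residue_index <= residueInterval[2]
  }
  idx <- which(keep)
  if (requireNonEmpty && length(idx) == 0L)
    stop("selection is empty (atom '", atomName, "')")
  idx
}

#' Atom indices of a named domain
#'
#' Convenience wrapper combining a [DomainMap-class] lookup with
#' [selectAtoms()]; `"FPT"` selects the fingers + palm + thumb composite.
#'
#' @param structure [ProteinStructure-class] or [MDTrajectory-class].
#' @param map a [DomainMap-class].
#' @param domain domain name (or "FPT").
#' @param atomName atom name (default "CA").
#' @return integer atom indices.
#' @export
domainAtomIndices <- function(structure, map, domain, atomName = "CA") {
  selectAtoms(structure, atomName = atomName,
              residues = domainResidues(map, domain))
}
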