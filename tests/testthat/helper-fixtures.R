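# In-code fixtures shared across test files.

suppressPackageStartupMessages(library(mclust))  # independent GMM cross-check

# straight CA chain: residue i at (i, 0, 0)
caChain <- function(n, identifier = "chain") {
  ProteinStructure(
    atoms = data.frame(residue_index = seq_len(n), residue_name = "ALA",
                       atom_name = "CA"),
    coords = cbind(seq_len(n), 0, 0), identifier = identifier)
}

# trajectory from a list of n x 3 coordinate matrices over one topology
trajFromFrames <- function(topology, frames, ...) {
  arr <- array(NA_real_, dim = c(length(frames), nAtoms(topology), 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  MDTrajectory(topology, arr, ...)
}

# random proper rotation matrix
randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# small two-domain spec used where a full miniature system would be overkill
twoDomainSpec <- function(K2translation = c(10, 0, 0), sigma = 0,
                          framesPerRun = 50L, seed = 1L,
                          transition = rbind(c(0.8, 0.2), c(0.2, 0.8))) {
  sizes <- c(A = 10L, B = 10L)
  topo <- buildToyTopology(sizes, centers = list(A = c(0, 0, 0),
                                                 B = c(30, 0, 0)))
  map <- toyDomainMap(sizes)
  jit <- c(A = sigma, B = sigma)
  states <- list(
    StateSpec(jitter = jit),
    StateSpec(list(B = domainTransform(0, c(0, 0, 1), K2translation)), jit))
  EnsembleSpec(topo, map, states, transition, framesPerRun = framesPerRun,
               runsPerCondition = c(apo = 1L), seed = seed)
}

# hand-written three-atom PDB text
writeTinyPDB <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00",
    "ATOM      3  CA  GLY A   2       4.125   3.250   3.000  1.00  0.00",
    "END"), path)
  path
}
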