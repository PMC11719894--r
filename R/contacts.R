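## Interdomain contact detection on all-atom structures: salt bridges
## (basic N within cutoff of acidic O) and hydrophobic side-chain
## carbon-carbon contacts.

basicNitrogens <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                       HIS = c("ND1", "NE2"))
acidicOxygens <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

chargedAtomRows <- function(a, groups) {
  keep <- rep(FALSE, nrow(a))
  for (res in names(groups))
    keep <- keep | (a$residue_name == res & a$atom_name %in% groups[[res]])
  which(keep)
}

crossContactTable <- function(structure, rowsA, rowsB, cutoff, op = `<=`) {
  a <- atomData(structure)
  X <- coords(structure)
  if (!length(rowsA) || !length(rowsB)) return(emptyContactTable())
  D <- crossDistances(X[rowsA, , drop = FALSE], X[rowsB, , drop = FALSE])
  hit <- which(op(D, cutoff), arr.ind = TRUE)
  if (!nrow(hit)) return(emptyContactTable())
  ia <- rowsA[hit[, 1]]; ib <- rowsB[hit[, 2]]
  out <- data.frame(
    resA = a$residue_index[ia], resnameA = a$residue_name[ia],
    atomA = a$atom_name[ia],
    resB = a$residue_index[ib], resnameB = a$residue_name[ib],
    atomB = a$atom_name[ib],
    distance = D[hit])
  out[order(out$resA, out$resB, out$distance), , drop = FALSE]
}

emptyContactTable <- function() {
  data.frame(resA = integer(), resnameA = character(), atomA = character(),
             resB = integer(), resnameB = character(), atomB = character(),
             distance = numeric())
}

#' Interdomain salt bridges
#'
#' Pairs where a basic-group nitrogen (Lys NZ; Arg NE/NH1/NH2; His
#' ND1/NE2) of one domain lies within `cutoff` of an acidic-group oxygen
#' (Asp OD1/OD2; Glu OE1/OE2) of the other, in either direction; the
#' result is invariant under swapping the two domains. Requires side-chain
#' atoms: CA-only structures yield an empty table with a warning.
#'
#' @param structure a [ProteinStructure-class] with side-chain atoms.
#' @param map a [DomainMap-class].
#' @param domainA,domainB domain names.
#' @param cutoff N-O distance cutoff, Angstrom (default 4.0, the common
#'   literature convention).
#' @return data.frame with columns resA, resnameA, atomA, resB, resnameB,
#'   atomB, distance; A-side atoms belong to `domainA`.
#' @export
findSaltBridges <- function(structure, map, domainA, domainB, cutoff = 4.0) {
  a <- atomData(structure)
  if (all(a$atom_name == "CA")) {
    warning("structure has no side-chain atoms; salt bridges skipped")
    return(emptyContactTable())
  }
  resA <- domainResidues(map, domainA)
  resB <- domainResidues(map, domainB)
  inA <- a$residue_index %in% resA
  inB <- a$residue_index %in% resB
  basics <- chargedAtomRows(a, basicNitrogens)
  acids <- chargedAtomRows(a, acidicOxygens)
  rbind(
    crossContactTable(structure, intersect(basics, which(inA)),
                      intersect(acids, which(inB)), cutoff),
    crossContactTable(structure, intersect(acids, which(inA)),
                      intersect(basics, which(inB)), cutoff))
}

#' Interdomain hydrophobic side-chain contacts
#'
#' Cross-domain residue pairs with any side-chain carbon-carbon distance
#' within `cutoff`, both residues drawn from a configurable hydrophobic
#' set. The default set is Ala, Val, Leu, Ile, Pro, Phe, Met, Trp; extend
#' it to include, e.g., the aliphatic stem of Lys. Symmetric in domain
#' order. CA-only structures yield an empty table with a warning.
#'
#' @param structure a [ProteinStructure-class] with side-chain atoms.
#' @param map a [DomainMap-class].
#' @param domainA,domainB domain names.
#' @param cutoff C-C distance cutoff, Angstrom (default 4.5).
#' @param hydrophobicSet 3-letter residue codes counted as hydrophobic.
#' @return data.frame as in [findSaltBridges()], one row per contacting
#'   atom pair (deduplicate on residue pairs as needed).
#' @export
findHydrophobicContacts <- function(structure, map, domainA, domainB,
                                    cutoff = 4.5,
                                    hydrophobicSet = c("ALA", "VAL", "LEU",
                                                       "ILE", "PRO", "PHE",
                                                       "MET", "TRP")) {
  a <- atomData(structure)
  if (all(a$atom_name == "CA")) {
    warning("structure has no side-chain atoms; hydrophobic contacts skipped")
    return(emptyContactTable())
  }
  known <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")
  odd <- setdiff(hydrophobicSet, known)
  if (length(odd)) {
    warning("ignoring unknown residue(s) in hydrophobic set: ",
            paste(odd, collapse = ", "))
    hydrophobicSet <- intersect(hydrophobicSet, known)
  }
  sideC <- a$atom_name != "CA" & a$atom_name != "C" &
    startsWith(a$atom_name, "C") & a$residue_name %in% hydrophobicSet
  inA <- a$residue_index %in% domainResidues(map, domainA)
  inB <- a$residue_index %in% domainResidues(map, domainB)
  crossContactTable(structure, which(sideC & inA), which(sideC & inB),
                    cutoff)
}
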