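# Internal helpers: constructors, residue chemistry tables, subsetting.

# Bondi van der Waals radii (A) for the elements that occur in heavy-atom
# protein models; anything else falls back to 1.8 A.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
.VDW_DEFAULT <- 1.8

vdwRadius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

# Unique residue key (chain|resno|icode) per atom, in file order.
residueKeys <- function(x) {
  a <- if (is(x, "ProteinStructure")) x@atoms else x
  paste(a$chain, a$resno, a$insert, sep = "|")
}

# Build a ProteinStructure from an atom table and either an n x 3 matrix or
# an n x 3 x m array.
newStructure <- function(atoms, xyz) {
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3L, 1L))
  rownames(atoms) <- NULL
  new("ProteinStructure", atoms = atoms, xyz = xyz)
}

# Minimal atom-table row builder used by fixtures and tests.
atomRow <- function(elety, elesy, resid, chain, resno,
                    insert = "", alt = "", occ = 1, b = 20) {
  data.frame(elety = elety, elesy = elesy, resid = resid, chain = chain,
             resno = as.integer(resno), insert = insert, alt = alt,
             occ = occ, b = b, stringsAsFactors = FALSE)
}

# Subset a structure (all models) by a logical or integer atom index.
subsetAtoms <- function(s, idx) {
  if (is.logical(idx)) idx <- which(idx)
  if (!length(idx)) stop("atom subset is empty")
  newStructure(s@atoms[idx, , drop = FALSE],
               s@xyz[idx, , , drop = FALSE])
}

# Subset a structure to a set of residue numbers (keeps file order).
subsetResidues <- function(s, resnos) {
  subsetAtoms(s, s@atoms$resno %in% resnos)
}

# Indices of one named atom per residue (NA where absent), residues in file
# order.  Used for Calpha extraction throughout.
atomIndexByResidue <- function(s, name = "CA") {
  keys <- residueKeys(s)
  ukeys <- unique(keys)
  hit <- which(s@atoms$elety == name)
  m <- match(ukeys, keys[hit])
  out <- hit[m]
  names(out) <- ukeys
  out
}

# Calpha coordinate matrix (one model), rows named by resno.
caCoords <- function(s, model = 1L) {
  idx <- atomIndexByResidue(s, "CA")
  idx <- idx[!is.na(idx)]
  m <- coords(s, model)[idx, , drop = FALSE]
  rownames(m) <- s@atoms$resno[idx]
  m
}

# ---- residue connectivity templates -------------------------------------
# Heavy-atom side-chain bonds for the 20 standard residues; backbone
# N-CA, CA-C, C-O (+ C-OXT) and the peptide link C(i)-N(i+1) are added
# programmatically.
.SIDECHAIN_BONDS <- list(
  GLY = NULL,
  ALA = list(c("CA", "CB")),
  SER = list(c("CA", "CB"), c("CB", "OG")),
  CYS = list(c("CA", "CB"), c("CB", "SG")),
  THR = list(c("CA", "CB"), c("CB", "OG1"), c("CB", "CG2")),
  VAL = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2")),
  LEU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  ILE = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
  MET = list(c("CA", "CB"), c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  PRO = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
  PHE = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
  TYR = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"),
             c("CZ", "OH")),
  TRP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "NE1"), c("NE1", "CE2"), c("CD2", "CE2"),
             c("CD2", "CE3"), c("CE2", "CZ2"), c("CE3", "CZ3"),
             c("CZ2", "CH2"), c("CZ3", "CH2")),
  ASP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  ASN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
  GLU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "OE2")),
  GLN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "NE2")),
  LYS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "CE"),
             c("CE", "NZ")),
  ARG = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "NE"),
             c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2")),
  HIS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"),
             c("ND1", "CE1"), c("CD2", "NE2"), c("CE1", "NE2"))
)

# Rigid/planar atom groups per residue type; all intra-group pairs get
# tier-2 (angle-tight) bounds.  The peptide plane is added programmatically.
.PLANAR_GROUPS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  ARG = list(c("NE", "CZ", "NH1", "NH2")),
  ASP = list(c("CB", "CG", "OD1", "OD2")),
  ASN = list(c("CB", "CG", "OD1", "ND2")),
  GLU = list(c("CG", "CD", "OE1", "OE2")),
  GLN = list(c("CG", "CD", "OE1", "NE2"))
)

# Residue types whose side chains are kept in "reliable" mode: broadly those
# with few well occupied rotamers, so their conformation is more likely to
# be maintained in a homologue.
.RELIABLE_SIDECHAINS <- c("CYS", "MET", "PHE", "TRP", "TYR",
                          "ILE", "LEU", "VAL", "PRO")

.POLYALA_ATOMS <- c("N", "CA", "C", "O", "CB")
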