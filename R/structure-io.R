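#' Read a protein structure from a PDB file
#'
#' Parses fixed-column PDB (\code{ATOM}/\code{HETATM}/\code{MODEL}/
#' \code{ENDMDL}) via \pkg{bio3d} into a [ProteinStructure-class].
#' \code{MODEL} blocks become separate coordinate sets sharing one atom
#' topology.  Hydrogens (and deuteriums) are dropped on read: all downstream
#' logic is heavy-atom only.
#'
#' @param path path to a PDB file.
#' @return a [ProteinStructure-class].
#' @details Fails with an informative error on files with no \code{ATOM}/
#'   \code{HETATM} records and on multi-MODEL files whose models disagree in
#'   atom count (inconsistent topology).
#' @examples
#' h <- makeHelix(5)
#' f <- tempfile(fileext = ".pdb")
#' writeModels(h, f)
#' s <- readPDB(f)
#' nResidues(s)
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # topology pre-check across MODEL blocks
  model_starts <- which(rec == "MODEL ")
  n_models <- max(1L, length(model_starts))
  if (n_models > 1L) {
    model_id <- findInterval(which(is_atom), model_starts)
    counts <- tabulate(model_id, nbins = n_models)
    if (length(unique(counts)) != 1L)
      stop("inconsistent topology: MODEL blocks contain ",
           paste(unique(counts), collapse = "/"), " atoms")
  }

  pdb <- bio3d::read.pdb(path, multi = n_models > 1L, rm.alt = FALSE,
                         verbose = FALSE)
  a <- pdb$atom
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)

  elesy <- a$elesy
  miss <- is.na(elesy) | !nzchar(trimws(elesy))
  if (any(miss)) elesy[miss] <- inferElement(a$elety[miss])
  elesy <- toupper(trimws(elesy))

  atoms <- data.frame(
    elety = trimws(a$elety), elesy = elesy, resid = trimws(a$resid),
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    alt = ifelse(is.na(a$alt), "", a$alt),
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE)

  n <- nrow(atoms)
  arr <- array(NA_real_, dim = c(n, 3L, nrow(xyz)))
  for (m in seq_len(nrow(xyz)))
    arr[, , m] <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)

  keep <- !(atoms$elesy %in% c("H", "D"))
  if (!any(keep)) stop("structure contains no heavy atoms")
  atoms$occ <- pmin(1, pmax(0, atoms$occ))
  newStructure(atoms[keep, , drop = FALSE], arr[keep, , , drop = FALSE])
}

# Element from atom name when columns 77-78 are blank: leading digits are
# stripped; names starting H (incl. 1HB2 etc.) are hydrogen.
inferElement <- function(elety) {
  nm <- sub("^[0-9]+", "", trimws(elety))
  first <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  out <- first
  out[two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CU")] <-
    two[two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CU")]
  out[first == "H"] <- "H"
  out
}

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Sanitize a structure for search-model generation
#'
#' Selects one chain and applies the preparation the distance-geometry
#' generator requires: selenomethionine (MSE) residues are reverted to
#' regular methionines (SE renamed SD, element S), for every
#' alternate-location group only the highest-occupancy conformer is kept
#' (ties broken by file order) and its altloc tag cleared, and waters plus
#' non-polymer heteroatoms are removed.  The operation is idempotent.
#'
#' @param s a [ProteinStructure-class].
#' @param chain chain identifier to retain; default: the first chain in the
#'   file.
#' @return the sanitized single-chain [ProteinStructure-class].
#' @examples
#' s <- makeHelix(8)
#' s2 <- prepareInput(s, "A")
#' @export
prepareInput <- function(s, chain = NULL) {
  stopifnot(is(s, "ProteinStructure"))
  a <- s@atoms
  if (is.null(chain)) chain <- a$chain[1]
  if (!chain %in% a$chain) stop("chain '", chain, "' not present")
  keep <- a$chain == chain & a$resid %in% c(.STANDARD_AA, "MSE")
  if (!any(keep)) stop("no polymer residues in chain '", chain, "'")
  s <- subsetAtoms(s, keep)
  a <- s@atoms

  # MSE -> MET (SE becomes SD, element S)
  mse <- a$resid == "MSE"
  if (any(mse)) {
    a$resid[mse] <- "MET"
    se <- mse & a$elety == "SE"
    a$elety[se] <- "SD"
    a$elesy[se] <- "S"
  }

  # altloc pruning: per residue+atom name keep the highest-occupancy
  # conformer (ties -> first in file order), then clear the tag
  grp <- paste(residueKeys(a), a$elety)
  ord <- order(match(grp, unique(grp)), -a$occ,
               seq_len(nrow(a)))  # stable: occ desc, file order
  first_of_grp <- !duplicated(grp[ord])
  keep_idx <- sort(ord[first_of_grp])
  s@atoms <- a
  s <- subsetAtoms(s, keep_idx)
  s@atoms$alt <- ""
  validObject(s)
  s
}

#' Write structures as PDB files
#'
#' Writes one or more coordinate sets in fixed-column PDB format.  With
#' \code{multiModel = TRUE} all coordinate sets are wrapped in
#' \code{MODEL}/\code{ENDMDL} records numbered 1..N (the ensemble
#' search-model format consumed by molecular-replacement programs);
#' otherwise a plain single-model PDB is written.  Coordinates are written
#' at the fixed-width 3-decimal PDB precision, so a read/write round trip
#' reproduces them to 0.001 A.
#'
#' @param models a [ProteinStructure-class] (possibly holding several
#'   models) or a list of structures sharing one topology.
#' @param path output file path.
#' @param multiModel logical; default \code{TRUE} whenever more than one
#'   coordinate set is supplied.
#' @return the path, invisibly.
#' @export
writeModels <- function(models, path, multiModel = NULL) {
  if (is(models, "ProteinStructure")) models <- list(models)
  if (!length(models)) stop("empty model list")
  atoms <- models[[1]]@atoms
  sets <- list()
  for (s in models) {
    stopifnot(is(s, "ProteinStructure"))
    if (nAtoms(s) != nrow(atoms))
      stop("models do not share one atom topology")
    for (m in seq_len(nModels(s))) sets[[length(sets) + 1L]] <- coords(s, m)
  }
  if (is.null(multiModel)) multiModel <- length(sets) > 1L
  if (!multiModel && length(sets) > 1L)
    stop("multiModel = FALSE requires a single coordinate set")

  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(sets)) {
    if (multiModel) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(formatAtomLines(atoms, sets[[m]]), con)
    writeLines(if (multiModel) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Fixed-column ATOM record formatting (columns per PDB v3.3).
formatAtomLines <- function(atoms, xyz) {
  name <- ifelse(nchar(atoms$elety) >= 4L | nchar(atoms$elesy) == 2L,
                 sprintf("%-4s", atoms$elety),
                 sprintf(" %-3s", atoms$elety))
  sprintf("ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(atoms)) %% 100000L, name,
          substr(paste0(atoms$alt, " "), 1, 1), atoms$resid, atoms$chain,
          atoms$resno, substr(paste0(atoms$insert, " "), 1, 1),
          xyz[, 1], xyz[, 2], xyz[, 3], atoms$occ, atoms$b,
          sprintf("%2s", atoms$elesy))
}
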