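#' Number of atoms, models and residues
#'
#' Accessors for the basic dimensions of a [ProteinStructure-class] (and so
#' also of a [ConformationEnsemble-class]).
#'
#' @param x a \code{ProteinStructure}.
#' @return integer scalar.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @rdname nAtoms
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Atom table accessor
#'
#' @param x a \code{ProteinStructure}.
#' @return the atom data.frame (one row per heavy atom).
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' Coordinate accessor
#'
#' @param x a \code{ProteinStructure}.
#' @param model integer, which coordinate set (default 1).
#' @return nAtoms x 3 numeric matrix, Angstrom.
#' @export
setGeneric("coords", function(x, model = 1L) standardGeneric("coords"))

#' Residue identifiers
#'
#' Author residue numbers in file order; the join key for score tables and
#' variance profiles.  Residues are identified by \code{resno} + insertion
#' code; the returned vector is the unique \code{resno} values (the package
#' requires unique resno+icode per chain, and single-chain inputs).
#'
#' @param x a \code{ProteinStructure}.
#' @return integer vector of residue numbers.
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

setMethod("nAtoms", "ProteinStructure", function(x) nrow(x@atoms))
setMethod("nModels", "ProteinStructure", function(x) dim(x@xyz)[3])
setMethod("nResidues", "ProteinStructure",
          function(x) length(unique(residueKeys(x))))
setMethod("atomData", "ProteinStructure", function(x) x@atoms)
setMethod("coords", "ProteinStructure", function(x, model = 1L) {
  stopifnot(model >= 1L, model <= dim(x@xyz)[3])
  m <- x@xyz[, , model, drop = FALSE]
  dim(m) <- dim(x@xyz)[1:2]
  colnames(m) <- c("x", "y", "z")
  m
})
setMethod("residueIds", "ProteinStructure", function(x) {
  k <- residueKeys(x)
  x@atoms$resno[!duplicated(k)]
})

setMethod("show", "ProteinStructure", function(object) {
  cat(sprintf("ProteinStructure: %d atoms, %d residues, %d model(s), chain(s) %s\n",
              nAtoms(object), nResidues(object), nModels(object),
              paste(unique(object@atoms$chain), collapse = ",")))
})

setMethod("show", "ConformationEnsemble", function(object) {
  cat(sprintf(
    "ConformationEnsemble: %d members (%d requested, %d discarded), %d atoms, %d residues\n",
    nModels(object), object@nRequested, object@nDiscarded,
    nAtoms(object), nResidues(object)))
  if (length(object@maxViolations))
    cat(sprintf("  worst residual violation: %.4f A\n",
                max(object@maxViolations)))
})

setMethod("show", "ConstraintSet", function(object) {
  cs <- object@constraints
  cat(sprintf("ConstraintSet: %d constraints over %d atoms\n",
              nrow(cs), object@nAtoms))
  if (nrow(cs)) {
    tb <- table(factor(cs$tier, levels = 1:5))
    cat("  by tier:", paste(sprintf("t%d=%d", 1:5, as.integer(tb)),
                            collapse = " "), "\n")
  }
})

setMethod("show", "ClusterSet", function(object) {
  sizes <- vapply(object@members, length, integer(1))
  cat(sprintf("ClusterSet: %d cluster(s), sizes %s, cutoff %.2f A\n",
              length(sizes), paste(sizes, collapse = "/"), object@cutoff))
})

setMethod("show", "SearchModel", function(object) {
  cat(sprintf(
    "SearchModel %s: %d residues, %d member(s), side chains '%s'%s\n",
    object@label, object@nResidues, nModels(object@model),
    object@sideChainMode,
    if (is.na(object@subclusterRadius)) ""
    else sprintf(", subcluster radius %.1f A", object@subclusterRadius)))
})
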