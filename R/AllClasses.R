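#' @import methods
NULL

#' Hierarchical protein structure with one or more coordinate sets
#'
#' The central container of the package: a flat atom table (one row per
#' heavy atom) plus a coordinate array holding one or more models that share
#' that atom topology.  Multi-MODEL PDB files map onto the third dimension of
#' \code{xyz}.
#'
#' @slot atoms data.frame with one row per atom and columns \code{elety}
#'   (atom name), \code{elesy} (element symbol), \code{resid} (3-letter
#'   residue code), \code{chain}, \code{resno} (author residue number),
#'   \code{insert} (insertion code, \code{""} if none), \code{alt}
#'   (alternate-location tag, \code{""} if none), \code{occ} (occupancy),
#'   \code{b} (isotropic B factor, A^2).
#' @slot xyz numeric array of dimension \code{c(nAtoms, 3, nModels)},
#'   coordinates in Angstrom.
#'
#' @seealso [readPDB()], [prepareInput()], [writeModels()]
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", xyz = "array"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("elety", "elesy", "resid", "chain", "resno", "insert", "alt",
            "occ", "b")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1L) return("structure must contain at least one atom")
  d <- dim(object@xyz)
  if (length(d) != 3L || d[1] != nrow(a) || d[2] != 3L)
    return("xyz must be an nAtoms x 3 x nModels array")
  if (!all(is.finite(object@xyz))) return("coordinates must be finite")
  if (any(a$occ < 0 | a$occ > 1)) return("occupancy must lie in [0, 1]")
  if (any(!nzchar(a$elesy))) return("element symbols must be non-empty")
  TRUE
})

#' Tiered interatomic distance bounds extracted from one structure
#'
#' Tier 1 covers covalent bonds (tightest bounds), tier 2 bond angles and
#' rigid/planar groups, tier 3 1-4 pairs, tier 4 backbone hydrogen-bond
#' partners inside helix/strand elements, tier 5 all remaining close
#' heavy-atom contacts.  Unconstrained pairs are kept apart by a global
#' van der Waals exclusion floor.
#'
#' @slot constraints data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices, i < j), \code{lower}, \code{upper} (A) and \code{tier}
#'   (integer 1-5).
#' @slot radii named numeric vector of per-element van der Waals radii (A)
#'   used for the exclusion floor.
#' @slot nAtoms integer, number of atoms the indices refer to.
#' @seealso [extractConstraints()]
#' @export
setClass("ConstraintSet",
  representation(constraints = "data.frame", radii = "numeric",
                 nAtoms = "integer"))

setValidity("ConstraintSet", function(object) {
  cs <- object@constraints
  need <- c("i", "j", "lower", "upper", "tier")
  if (!all(need %in% names(cs)))
    return(paste("constraints must have columns:", paste(need, collapse = ", ")))
  if (nrow(cs)) {
    if (any(cs$i == cs$j)) return("self-constraints are not allowed")
    if (any(cs$lower <= 0) || any(cs$lower > cs$upper + 1e-12))
      return("bounds must satisfy 0 < lower <= upper")
    if (any(cs$tier < 1 | cs$tier > 5)) return("tier must be in 1..5")
    key <- paste(pmin(cs$i, cs$j), pmax(cs$i, cs$j))
    if (anyDuplicated(key)) return("at most one constraint per atom pair")
  }
  if (is.null(names(object@radii)) || !length(object@radii))
    return("radii must be a named vector")
  TRUE
})

#' Conformational ensemble produced by the distance-geometry generator
#'
#' Extends [ProteinStructure-class]: the shared atom table is the topology
#' and every slice of \code{xyz} is one accepted conformation.  Bookkeeping
#' slots record how the ensemble was produced.
#'
#' @slot nRequested integer, number of conformations asked for.
#' @slot nDiscarded integer, non-converged runs that were discarded.
#' @slot seeds integer vector, the per-member random seeds.
#' @slot nSweeps integer vector, correction sweeps used per member.
#' @slot maxViolations numeric vector, final worst constraint violation (A)
#'   per member.
#' @seealso [generateEnsemble()], [makePerturbedEnsemble()]
#' @export
setClass("ConformationEnsemble", contains = "ProteinStructure",
  representation(nRequested = "integer", nDiscarded = "integer",
                 seeds = "integer", nSweeps = "integer",
                 maxViolations = "numeric"))

#' Result of clustering ensemble members
#'
#' @slot members list of integer vectors, one per cluster, ordered by
#'   decreasing size (ties broken by lowest centroid index).
#' @slot centroids integer vector, the centroid member index of each cluster.
#' @slot cutoff numeric, the pairwise Calpha-RMSD cutoff (A) actually used
#'   after auto-tuning.
#' @seealso [clusterEnsemble()]
#' @export
setClass("ClusterSet",
  representation(members = "list", centroids = "integer", cutoff = "numeric"))

setValidity("ClusterSet", function(object) {
  if (length(object@members) != length(object@centroids))
    return("one centroid per cluster required")
  all_m <- unlist(object@members)
  if (anyDuplicated(all_m)) return("clusters must be disjoint")
  TRUE
})

#' A truncated, side-chain-processed search model
#'
#' One element of a search-model pool: a single model or a multi-MODEL
#' ensemble, after residue truncation and side-chain treatment, plus the
#' provenance needed to name and trace it.
#'
#' @slot model [ProteinStructure-class] holding 1..cap coordinate sets.
#' @slot nResidues integer, residues retained.
#' @slot sideChainMode one of \code{"allatom"}, \code{"reliable"},
#'   \code{"polyala"}.
#' @slot subclusterRadius numeric (A), \code{NA} for single-structure mode.
#' @slot clusterIndex integer, source cluster (\code{NA} in single-structure
#'   mode).
#' @slot scoreColumn character, name of the score column that drove the
#'   truncation.
#' @slot label character, unique provenance label (also the output filename
#'   stem).
#' @seealso [buildSearchModels()], [truncateSingleModel()]
#' @export
setClass("SearchModel",
  representation(model = "ProteinStructure", nResidues = "integer",
                 sideChainMode = "character", subclusterRadius = "numeric",
                 clusterIndex = "integer", scoreColumn = "character",
                 label = "character"))

setValidity("SearchModel", function(object) {
  if (!object@sideChainMode %in% c("allatom", "reliable", "polyala"))
    return("sideChainMode must be allatom, reliable or polyala")
  if (object@nResidues < 1L) return("a search model keeps at least 1 residue")
  TRUE
})
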