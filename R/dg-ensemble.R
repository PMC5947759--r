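#' Sample one conformation satisfying a constraint set
#'
#' One run of the distance-geometry generator: the start coordinates are
#' displaced by isotropic Gaussian noise (sd \code{sigma} per atom), then
#' corrections are applied sweep by sweep until every bound is satisfied.
#' Within a sweep the violated pairs are visited in (seeded) random order;
#' for a pair at distance d outside its bounds, both atoms are moved along
#' the pair axis by (d - t)/2 each, t being the nearest bound.  Exclusion
#' violations are treated as lower-bound constraints.  A chirality guard
#' mirrors all coordinates whenever the majority of Calpha centres (signed
#' volume of N, C, CB about CA) invert relative to the input structure, and
#' correction continues.  Runs that have not converged after
#' \code{maxSweeps} sweeps are reported as failures (a signalled outcome,
#' not an error): the caller restarts with a new seed.
#'
#' @param cs a [ConstraintSet-class] from [extractConstraints()].
#' @param s the generating [ProteinStructure-class] (supplies start
#'   positions, element radii and the chirality reference).
#' @param seed integer seed; the run is deterministic given the seed.
#' @param start optional nAtoms x 3 start coordinates (default: the input
#'   structure's).
#' @param sigma initial random displacement sd per atom (A); 0 starts from
#'   \code{start} unperturbed.
#' @param maxSweeps sweep cap before the run is declared non-converged.
#' @param tol convergence tolerance (A): accepted conformations violate no
#'   bound by more than this.
#' @return list with elements \code{xyz} (nAtoms x 3), \code{converged},
#'   \code{nSweeps}, \code{maxViolation} (A), \code{seed}.
#' @examples
#' h <- makeHelix(6)
#' cs <- extractConstraints(h)
#' conf <- sampleConformation(cs, h, seed = 1)
#' conf$maxViolation
#' @export
sampleConformation <- function(cs, s, seed = 1L, start = NULL,
                               sigma = 1.5, maxSweeps = 500L, tol = 0.05) {
  stopifnot(is(cs, "ConstraintSet"), is(s, "ProteinStructure"))
  if (is.null(start)) start <- coords(s, 1L)
  stopifnot(nrow(start) == cs@nAtoms)
  radii <- vdwRadius(s@atoms$elesy)
  chir <- chiralityCenters(s)
  res <- .dg_sample(start, cs@constraints$i, cs@constraints$j,
                    cs@constraints$lower, cs@constraints$upper,
                    radii, constraintParams()$exclusionFactor,
                    sigma, as.integer(seed), as.integer(maxSweeps), tol,
                    chir$centers, chir$ref)
  list(xyz = res$xyz, converged = res$converged, nSweeps = res$nSweeps,
       maxViolation = res$maxViolation, seed = as.integer(seed))
}

# Chirality centres (CA, N, C, CB index quadruples) and their reference
# signed-volume signs in the input structure.
chiralityCenters <- function(s) {
  iCA <- atomIndexByResidue(s, "CA"); iN <- atomIndexByResidue(s, "N")
  iC <- atomIndexByResidue(s, "C"); iCB <- atomIndexByResidue(s, "CB")
  ok <- !(is.na(iCA) | is.na(iN) | is.na(iC) | is.na(iCB))
  centers <- cbind(iCA[ok], iN[ok], iC[ok], iCB[ok])
  if (!nrow(centers))
    return(list(centers = matrix(integer(0), ncol = 4L), ref = numeric(0)))
  x <- coords(s, 1L)
  ref <- apply(centers, 1L, function(r) {
    v <- det(rbind(x[r[2], ] - x[r[1], ], x[r[3], ] - x[r[1], ],
                   x[r[4], ] - x[r[1], ]))
    if (v >= 0) 1 else -1
  })
  list(centers = centers, ref = as.numeric(ref))
}

#' Fraction of Calpha centres retaining the input handedness
#'
#' @param s the generating structure (reference).
#' @param xyz candidate coordinates (nAtoms x 3).
#' @return fraction in [0, 1]; 1 means chirality fully preserved.
#' @export
chiralityPreserved <- function(s, xyz) {
  chir <- chiralityCenters(s)
  if (!nrow(chir$centers)) return(1)
  signs <- apply(chir$centers, 1L, function(r) {
    v <- det(rbind(xyz[r[2], ] - xyz[r[1], ], xyz[r[3], ] - xyz[r[1], ],
                   xyz[r[4], ] - xyz[r[1], ]))
    if (v >= 0) 1 else -1
  })
  mean(signs == chir$ref)
}

#' Generate a conformational ensemble from one structure
#'
#' Expands a single sanitized structure into an ensemble of \code{n}
#' conformations, each satisfying the tiered distance constraints extracted
#' from the input.  Per-member child seeds are derived as
#' \code{seed + attempt index}, so the result is fully deterministic given
#' \code{(seed, n)}; non-converging runs are discarded and restarted with
#' the next child seed, up to a restart budget of \code{10 * n} attempts.
#'
#' @param s sanitized single-model [ProteinStructure-class].
#' @param n number of conformations (default 500).
#' @param seed root seed.
#' @param params constraint parameters ([constraintParams()]).
#' @param sigma,maxSweeps,tol see [sampleConformation()].
#' @param cs optional pre-computed [ConstraintSet-class].
#' @return a [ConformationEnsemble-class] with exactly \code{n} members.
#' @examples
#' e <- generateEnsemble(makeHelix(8), n = 3, seed = 1)
#' nModels(e)
#' @export
generateEnsemble <- function(s, n = 500L, seed = 1L,
                             params = constraintParams(), sigma = 1.5,
                             maxSweeps = 500L, tol = 0.05, cs = NULL) {
  stopifnot(is(s, "ProteinStructure"), n >= 1L)
  if (is.null(cs)) cs <- extractConstraints(s, params)
  nat <- nAtoms(s)
  arr <- array(NA_real_, dim = c(nat, 3L, n))
  seeds <- integer(n); sweeps <- integer(n); viol <- numeric(n)
  got <- 0L; attempt <- 0L; budget <- 10L * n
  while (got < n && attempt < budget) {
    child <- as.integer(seed) + attempt
    conf <- sampleConformation(cs, s, seed = child, sigma = sigma,
                               maxSweeps = maxSweeps, tol = tol)
    attempt <- attempt + 1L
    if (!conf$converged) next
    got <- got + 1L
    arr[, , got] <- conf$xyz
    seeds[got] <- child; sweeps[got] <- conf$nSweeps
    viol[got] <- conf$maxViolation
  }
  if (got < n)
    stop("restart budget exhausted: ", got, "/", n,
         " conformations converged in ", budget, " attempts")
  new("ConformationEnsemble", atoms = s@atoms, xyz = arr,
      nRequested = as.integer(n), nDiscarded = attempt - got,
      seeds = seeds, nSweeps = sweeps, maxViolations = viol)
}

#' Write ensemble members as numbered PDB files
#'
#' @param e a [ConformationEnsemble-class].
#' @param dir output directory (created if needed).
#' @param stem filename stem; files are named \code{stem_disco<i>.pdb}.
#' @return character vector of paths, invisibly.
#' @export
writeEnsembleFiles <- function(e, dir, stem = "model") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nModels(e))
  for (m in seq_len(nModels(e))) {
    paths[m] <- file.path(dir, sprintf("%s_disco%d.pdb", stem, m))
    writeModels(newStructure(e@atoms, coords(e, m)), paths[m],
                multiModel = FALSE)
  }
  invisible(paths)
}
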