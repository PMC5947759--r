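# Synthetic-structure generators: every stage of the package is testable
# without downloading any deposited structure.

# Place atom D given A-B-C, bond length r (C-D), bond angle theta (B-C-D,
# degrees) and dihedral chi (A-B-C-D, degrees).  Standard NeRF construction.
.nerf <- function(A, B, C, r, theta, chi) {
  theta <- theta * pi / 180; chi <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d <- r * c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi))
  C + d[1] * bc + d[2] * m2 + d[3] * n
}

# Ideal backbone geometry (Engh-Huber-like values).
.GEO <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
             ca_cb = 1.530, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
             ang_c_n_ca = 121.7, ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5,
             chi_cb = -122.6)

# Build an all-ALA chain from phi/psi vectors (degrees); omega fixed trans.
buildChain <- function(phi, psi, chain = "A", resnoStart = 1L) {
  n <- length(phi)
  stopifnot(n >= 1L, length(psi) == n)
  g <- .GEO
  pos <- vector("list", n)
  N <- c(0, 0, 0); CA <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C <- CA + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      prev <- pos[[i - 1L]]
      N <- .nerf(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n, psi[i - 1L])
      CA <- .nerf(prev$CA, prev$C, N, g$n_ca, g$ang_c_n_ca, 180)
      C <- .nerf(prev$C, N, CA, g$ca_c, g$ang_n_ca_c, phi[i])
    }
    O <- .nerf(N, CA, C, g$c_o, g$ang_ca_c_o, psi[i] + 180)
    CB <- .nerf(C, N, CA, g$ca_cb, g$ang_n_ca_cb, g$chi_cb)
    pos[[i]] <- list(N = N, CA = CA, C = C, O = O, CB = CB)
  }
  names_per_res <- c("N", "CA", "C", "O", "CB")
  atoms <- do.call(rbind, lapply(seq_len(n), function(i)
    atomRow(names_per_res, c("N", "C", "C", "O", "C"), "ALA", chain,
            resnoStart + i - 1L)))
  xyz <- do.call(rbind, lapply(seq_len(n), function(i)
    do.call(rbind, pos[[i]][names_per_res])))
  newStructure(atoms, xyz)
}

#' Ideal alpha-helix fixture
#'
#' Builds an all-alanine ideal alpha-helix (backbone + CB, canonical bond
#' lengths and angles, phi = -57, psi = -47: ~100 degree twist and ~1.5 A
#' rise per residue), optionally followed by an extended (strand-like,
#' unpaired) tail.  The result is PDB-writable and round-trips through
#' [readPDB()]/[writeModels()].
#'
#' @param nRes number of helical residues (>= 1).
#' @param tailRes number of extended tail residues appended (default 0).
#' @return a [ProteinStructure-class] with \code{nRes + tailRes} residues.
#' @examples
#' h <- makeHelix(15)
#' d <- dist(caCoordinates(h)[1:2, ])  # consecutive CA-CA ~ 3.8 A
#' @export
makeHelix <- function(nRes, tailRes = 0L) {
  if (nRes < 1L) stop("nRes must be >= 1")
  phi <- c(rep(-57, nRes), rep(-139, tailRes))
  psi <- c(rep(-47, nRes), rep(135, tailRes))
  buildChain(phi, psi)
}

#' Antiparallel two-strand fixture
#'
#' Two extended strands (phi = -139, psi = 135) arranged antiparallel at
#' canonical backbone hydrogen-bonding registry, used to exercise strand (E)
#' assignment.  The second strand is the first rotated 180 degrees about the
#' strand axis and offset so that N-H...O=C pairs form across the two
#' strands.  Antiparallel sheets have a two-fold axis perpendicular to the
#' sheet plane, so the partner is generated by a 180-degree rotation about
#' z followed by an in-plane offset fixed (by construction, against the
#' Kabsch-Sander energy of the ideal extended geometry) at hydrogen-bonding
#' registry.
#'
#' @param nRes residues per strand (default 6).
#' @return a [ProteinStructure-class] with \code{2 * nRes} residues in one
#'   chain (numbered with a gap of 10 between the strands).
#' @export
makeStrandPair <- function(nRes = 6L) {
  s1 <- buildChain(rep(-139, nRes), rep(135, nRes))
  x1 <- coords(s1)
  x2 <- x1 %*% diag(c(-1, -1, 1))
  x2[, 1] <- x2[, 1] + .STRAND_PAIR_OFFSET["x"]
  x2[, 2] <- x2[, 2] + .STRAND_PAIR_OFFSET["y"]
  a2 <- s1@atoms
  a2$resno <- a2$resno + nRes + 10L
  atoms <- rbind(s1@atoms, a2)
  newStructure(atoms, rbind(x1, x2))
}

# In-plane offsets (A) of the rotated partner strand; chosen once so that
# cross-strand N-H...O=C bonds form without steric clash for nRes = 6.
.STRAND_PAIR_OFFSET <- c(x = 14.0, y = 3.8)

#' Gaussian-perturbed synthetic ensemble
#'
#' Replicates one structure n times and displaces every atom of residue r by
#' iid Gaussian noise with standard deviation \code{sigmaProfile[r]}.  This
#' is the parameter-recovery harness for the variance estimator: the noise
#' is not physically realistic (no bonded-geometry restoration), which is
#' sufficient because downstream code consumes only coordinates.
#'
#' @param s a single-model [ProteinStructure-class].
#' @param n number of members.
#' @param sigmaProfile per-residue displacement sd (A): either a single
#'   value, a vector of length \code{nResidues(s)}, or a vector named by
#'   residue number.
#' @param seed integer seed; equal seeds give identical ensembles.
#' @return a [ConformationEnsemble-class] with \code{n} members.
#' @examples
#' e <- makePerturbedEnsemble(makeHelix(10), 5, 0.3, seed = 1)
#' nModels(e)
#' @export
makePerturbedEnsemble <- function(s, n, sigmaProfile, seed = 1L) {
  stopifnot(is(s, "ProteinStructure"), n >= 1L)
  rids <- residueIds(s)
  if (length(sigmaProfile) == 1L)
    sigmaProfile <- rep(sigmaProfile, length(rids))
  if (!is.null(names(sigmaProfile)))
    sigmaProfile <- sigmaProfile[as.character(rids)]
  if (length(sigmaProfile) != length(rids))
    stop("sigmaProfile must map onto the residues of s")
  if (any(is.na(sigmaProfile)) || any(sigmaProfile < 0))
    stop("sigmaProfile must be non-negative")
  sd_atom <- sigmaProfile[match(s@atoms$resno, rids)]
  base <- coords(s, 1L)
  nat <- nAtoms(s)
  arr <- array(NA_real_, dim = c(nat, 3L, n))
  set.seed(seed)
  for (m in seq_len(n))
    arr[, , m] <- base + matrix(stats::rnorm(3L * nat, sd = sd_atom),
                                ncol = 3L)
  new("ConformationEnsemble", atoms = s@atoms, xyz = arr,
      nRequested = as.integer(n), nDiscarded = 0L,
      seeds = seq_len(n) + as.integer(seed),
      nSweeps = integer(n), maxViolations = numeric(n))
}

#' Calpha coordinates of a structure
#'
#' Convenience accessor returning the Calpha coordinate matrix of one model,
#' rows named by residue number.
#'
#' @param s a [ProteinStructure-class].
#' @param model model index (default 1).
#' @return numeric matrix (nResidues x 3).
#' @export
caCoordinates <- function(s, model = 1L) caCoords(s, model)
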