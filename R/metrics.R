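# Built-in per-residue score generators: packing (weighted contact number),
# exposure (solvent-accessible surface area), crystallographic B factors.
# Each writes/returns the same table format the score-file parser reads.

#' Weighted contact number (packing) profile
#'
#' Per-residue packing density
#' \deqn{WCN_i = \sum_{j \ne i} 1 / d(C\alpha_i, C\alpha_j)^2 ,}
#' an inverse-square contact weight over all residue pairs.  Tightly packed
#' regions are more rigid and more evolutionarily conserved, so HIGH raw
#' WCN marks residues that should be KEPT.  Because the truncation contract
#' removes high-scoring residues first, the emitted \code{wcn} column is
#' the NEGATED raw WCN; set \code{raw = TRUE} for the positive values.
#'
#' @param s a [ProteinStructure-class].
#' @param center \code{"CA"} (default) or \code{"centroid"} (side-chain
#'   centroid, falling back to CA for glycine).
#' @param raw return the raw (positive) WCN instead of the negated score.
#' @return data.frame with columns \code{resno}, \code{wcn}.  Residues
#'   lacking the reference atom are excluded with a warning.
#' @examples
#' wcnProfile(makeHelix(10), raw = TRUE)
#' @export
wcnProfile <- function(s, center = c("CA", "centroid"), raw = FALSE) {
  center <- match.arg(center)
  if (center == "CA") {
    idx <- atomIndexByResidue(s, "CA")
    if (any(is.na(idx)))
      warning(sum(is.na(idx)), " residue(s) lack CA; excluded from WCN")
    keep <- !is.na(idx)
    pts <- coords(s, 1L)[idx[keep], , drop = FALSE]
    rids <- residueIds(s)[keep]
  } else {
    keys <- residueKeys(s)
    x <- coords(s, 1L)
    side <- !(s@atoms$elety %in% c("N", "CA", "C", "O"))
    ukeys <- unique(keys)
    pts <- t(vapply(ukeys, function(k) {
      w <- which(keys == k & side)
      if (!length(w)) w <- which(keys == k & s@atoms$elety == "CA")
      colMeans(x[w, , drop = FALSE])
    }, numeric(3)))
    rids <- residueIds(s)
    keep <- !apply(pts, 1, anyNA)
    pts <- pts[keep, , drop = FALSE]; rids <- rids[keep]
  }
  n <- nrow(pts)
  w <- if (n < 2L) rep(0, n) else {
    dm <- as.matrix(stats::dist(pts))
    diag(dm) <- Inf
    rowSums(1 / dm^2)
  }
  data.frame(resno = rids, wcn = if (raw) w else -w)
}

#' Solvent-accessible surface area profile (Shrake-Rupley)
#'
#' Residue ASA in A^2 by numerical quadrature: quasi-uniform points
#' (Fibonacci sphere) are placed on every atom's solvent-expanded sphere of
#' radius \eqn{r_{vdW} + probe}; a point is accessible iff it lies outside
#' every other atom's expanded sphere, and the atom's ASA is the accessible
#' fraction times the expanded-sphere area.  Residue ASA sums its atoms.
#' Exposed residues score high and are removed first, which matches the
#' truncation contract directly (no negation).
#'
#' @param s a [ProteinStructure-class].
#' @param probe solvent probe radius (A, default 1.4).
#' @param nPoints quadrature points per atom (default 960; the error
#'   roughly halves as the count quadruples).
#' @param relative divide by Gly-X-Gly maximum accessibility per residue
#'   type (relative solvent accessibility in [0, ~1]) instead of raw A^2.
#' @return data.frame with columns \code{resno}, \code{asa}.
#' @details Atoms of unknown element get a 1.8 A radius with a warning.
#' @export
sasaProfile <- function(s, probe = 1.4, nPoints = 960L, relative = FALSE) {
  a <- s@atoms
  x <- coords(s, 1L)
  unknown <- !(a$elesy %in% names(.VDW_RADII))
  if (any(unknown))
    warning("unknown element(s) ", paste(unique(a$elesy[unknown]), collapse = ","),
            ": using default radius 1.8 A")
  atomAsa <- shrakeRupley(x, vdwRadius(a$elesy), probe, nPoints)
  keys <- residueKeys(s)
  tot <- tapply(atomAsa, factor(keys, levels = unique(keys)), sum)
  out <- data.frame(resno = residueIds(s), asa = as.numeric(tot))
  if (relative) {
    resid1 <- a$resid[!duplicated(keys)]
    ref <- .MAX_ASA_GXG[resid1]
    ref[is.na(ref)] <- mean(.MAX_ASA_GXG)
    out$asa <- out$asa / ref
  }
  out
}

# Atom-wise Shrake-Rupley quadrature.
shrakeRupley <- function(x, radii, probe, nPoints) {
  sph <- fibonacciSphere(nPoints)
  n <- nrow(x)
  er <- radii + probe
  out <- numeric(n)
  dm <- as.matrix(stats::dist(x))
  for (i in seq_len(n)) {
    nb <- which(dm[i, ] < er[i] + er & seq_len(n) != i)
    pts <- sweep(sph * er[i], 2L, x[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      d2 <- (pts[, 1] - x[j, 1])^2 + (pts[, 2] - x[j, 2])^2 +
            (pts[, 3] - x[j, 3])^2
      acc <- acc & d2 > er[j]^2
      if (!any(acc)) break
    }
    out[i] <- mean(acc) * 4 * pi * er[i]^2
  }
  out
}

# Quasi-uniform unit-sphere point set (golden-angle spiral).
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Theoretical maximum ASA (A^2) in a Gly-X-Gly tripeptide (Tien et al.
# style values), used for relative solvent accessibility.
.MAX_ASA_GXG <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLN = 225,
  GLU = 223, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174)

#' Residue-averaged crystallographic B-factor profile
#'
#' Arithmetic mean of the heavy-atom isotropic B factors per residue.
#' High-B (mobile/poorly ordered) residues are removed first, matching the
#' truncation contract directly.
#'
#' @param s a [ProteinStructure-class].
#' @return data.frame with columns \code{resno}, \code{bfac}.
#' @export
bfactorProfile <- function(s) {
  keys <- residueKeys(s)
  m <- tapply(s@atoms$b, factor(keys, levels = unique(keys)), mean)
  data.frame(resno = residueIds(s), bfac = as.numeric(m))
}

#' Built-in metric dispatcher
#'
#' Computes the named built-in per-residue metrics and merges them into one
#' score table suitable for [truncateSingleModel()].
#'
#' @param s a sanitized [ProteinStructure-class].
#' @param which subset of \code{c("wcn", "asa", "bfac", "variance")}.
#' @param nStruct ensemble size used for the \code{"variance"} metric
#'   (which generates a distance-geometry ensemble and scores residues by
#'   [varianceProfile()]).
#' @param seed seed for the \code{"variance"} ensemble.
#' @return data.frame: \code{resno} + one column per requested metric.
#' @export
builtinMetrics <- function(s, which = c("wcn", "bfac"), nStruct = 100L,
                           seed = 1L) {
  which <- match.arg(which, c("wcn", "asa", "bfac", "variance"),
                     several.ok = TRUE)
  out <- data.frame(resno = residueIds(s))
  for (m in which) {
    prof <- switch(m,
      wcn = wcnProfile(s),
      asa = sasaProfile(s),
      bfac = bfactorProfile(s),
      variance = {
        e <- generateEnsemble(s, n = nStruct, seed = seed)
        varianceProfile(e)
      })
    out <- merge(out, prof, by = "resno", sort = TRUE)
  }
  out
}
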