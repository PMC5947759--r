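# Test-side oracles and fixture helpers, implemented independently of the
# package code paths they check.

# Hand-formatted PDB ATOM line (fixed columns), independent of the
# package's writer.
pdbLine <- function(serial, name, resid, chain, resno, x, y, z,
                    occ = 1, b = 20, ele = substr(name, 1, 1),
                    alt = " ", icode = " ", record = "ATOM  ") {
  nm <- if (nchar(name) >= 4) sprintf("%-4s", name) else sprintf(" %-3s", name)
  sprintf("%s%5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resid, chain, resno, icode,
          x, y, z, occ, b, sprintf("%2s", ele))
}

# Three-residue hand-written PDB (GLY backbone only), plus one hydrogen
# that readPDB must drop.
tinyPdbLines <- function() c(
  pdbLine(1, "N",  "GLY", "A", 1, 0.000, 0.000, 0.000, ele = "N"),
  pdbLine(2, "CA", "GLY", "A", 1, 1.458, 0.000, 0.000, ele = "C"),
  pdbLine(3, "C",  "GLY", "A", 1, 2.009, 1.420, 0.000, ele = "C"),
  pdbLine(4, "O",  "GLY", "A", 1, 1.251, 2.390, 0.000, ele = "O"),
  pdbLine(5, "H",  "GLY", "A", 1, -0.500, 0.800, 0.000, ele = "H"),
  pdbLine(6, "N",  "GLY", "A", 2, 3.332, 1.536, 0.000, ele = "N"),
  pdbLine(7, "CA", "GLY", "A", 2, 4.000, 2.800, 0.100, ele = "C"),
  pdbLine(8, "C",  "GLY", "A", 2, 5.500, 2.700, 0.050, ele = "C"),
  pdbLine(9, "O",  "GLY", "A", 2, 6.100, 1.650, 0.000, ele = "O"),
  pdbLine(10, "N",  "GLY", "A", 3, 6.150, 3.850, 0.000, ele = "N"),
  pdbLine(11, "CA", "GLY", "A", 3, 7.600, 3.900, 0.000, ele = "C"),
  pdbLine(12, "C",  "GLY", "A", 3, 8.200, 5.300, 0.000, ele = "C"),
  pdbLine(13, "O",  "GLY", "A", 3, 7.500, 6.320, 0.000, ele = "O"))

# Monte-Carlo solvent-accessible-area oracle: random (not Fibonacci) sphere
# points, independent of the package quadrature.
mcSasa <- function(xyz, radii, probe = 1.4, nPts = 40000L, seed = 99) {
  set.seed(seed)
  er <- radii + probe
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- matrix(rnorm(3L * nPts), ncol = 3L)
    v <- v / sqrt(rowSums(v^2))
    pts <- sweep(v * er[i], 2L, xyz[i, ], "+")
    acc <- rep(TRUE, nPts)
    for (j in setdiff(seq_len(n), i)) {
      acc <- acc & (rowSums(sweep(pts, 2L, xyz[j, ])^2) > er[j]^2)
    }
    out[i] <- mean(acc) * 4 * pi * er[i]^2
  }
  out
}

# Analytic accessible area of each of two intersecting spheres (expanded
# radii R1, R2, centre distance d): full sphere minus the buried cap.
twoSphereAsa <- function(R1, R2, d) {
  cap <- function(R, Ro) {
    h <- R - (d^2 + R^2 - Ro^2) / (2 * d)
    2 * pi * R * max(0, min(h, 2 * R))
  }
  c(4 * pi * R1^2 - cap(R1, R2), 4 * pi * R2^2 - cap(R2, R1))
}

# Brute-force weighted-contact-number oracle (explicit double loop).
bruteWcn <- function(ca) {
  n <- nrow(ca)
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    out[i] <- out[i] + 1 / sum((ca[i, ] - ca[j, ])^2)
  out
}

# Independent constraint-census oracle for all-ALA fixtures: bonds by
# distance (< 1.9 A), graph distances by boolean matrix powers, planar
# peptide-plane override, tier-4 from the ideal-helix i -> i+4 pattern,
# tier-5 by distance.  Returns the expected count per tier.
oracleConstraintCensus <- function(s, helixCore) {
  x <- caCoordinates(s)  # not used; keep residue order handy
  a <- atomData(s)
  xyz <- coords(s)
  n <- nrow(a)
  dm <- as.matrix(dist(xyz))
  A1 <- dm < 1.9; diag(A1) <- FALSE
  A2 <- (A1 %*% A1) > 0
  A3 <- (A2 %*% A1) > 0
  g1 <- A1
  g2 <- A2 & !A1; diag(g2) <- FALSE
  g3 <- A3 & !A2 & !A1; diag(g3) <- FALSE

  # peptide-plane pairs get tier 2 even at graph distance 3
  plane <- matrix(FALSE, n, n)
  for (r in seq_len(max(a$resno) - 1L)) {
    idx <- c(which(a$resno == r & a$elety %in% c("CA", "C", "O")),
             which(a$resno == r + 1L & a$elety %in% c("N", "CA")))
    for (p in idx) for (q in idx) if (p != q) plane[p, q] <- TRUE
  }
  t2 <- (g2 | (plane & !g1))
  t3 <- g3 & !t2

  # tier 4: ideal-helix N(i+4)...O(i) hydrogen bonds, both residues in the
  # helical core (labels known from the fixture's construction)
  t4pairs <- 0L
  for (i in seq_len(max(a$resno) - 4L))
    if ((i %in% helixCore) && ((i + 4L) %in% helixCore)) t4pairs <- t4pairs + 1L

  covered <- g1 | t2 | t3
  # mark tier-4 pairs as covered
  for (i in seq_len(max(a$resno) - 4L)) {
    if (!((i %in% helixCore) && ((i + 4L) %in% helixCore))) next
    p <- which(a$resno == i + 4L & a$elety == "N")
    q <- which(a$resno == i & a$elety == "O")
    covered[p, q] <- covered[q, p] <- TRUE
  }
  t5 <- dm < 6.0 & !covered; diag(t5) <- FALSE
  c(t1 = sum(g1) / 2, t2 = sum(t2) / 2, t3 = sum(t3) / 2,
    t4 = t4pairs, t5 = sum(t5) / 2)
}

# Random proper rotation matrix.
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Two-basin synthetic ensemble: nA members jittered about the base
# structure, nB about a scaled (structurally distant) copy.
twoBasinEnsemble <- function(base, nA, nB, scale = 3, jitter = 0.15,
                             seed = 7) {
  eA <- makePerturbedEnsemble(base, nA, jitter, seed = seed)
  big <- base
  big@xyz <- big@xyz * scale
  eB <- makePerturbedEnsemble(big, nB, jitter, seed = seed + 1L)
  arr <- array(NA_real_, dim = c(nAtoms(base), 3L, nA + nB))
  for (m in seq_len(nA)) arr[, , m] <- coords(eA, m)
  for (m in seq_len(nB)) arr[, , nA + m] <- coords(eB, m)
  new("ConformationEnsemble", atoms = base@atoms, xyz = arr,
      nRequested = as.integer(nA + nB), nDiscarded = 0L,
      seeds = seq_len(nA + nB), nSweeps = integer(nA + nB),
      maxViolations = numeric(nA + nB))
}
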