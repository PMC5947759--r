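#' Assign secondary structure (H/E/C) from backbone geometry
#'
#' Three-state secondary-structure assignment from backbone hydrogen-bond
#' patterns, in the Kabsch-Sander style: amide hydrogens are placed at the
#' ideal position (1.0 A from N, opposite the preceding carbonyl), the
#' electrostatic hydrogen-bond energy
#' \deqn{E = 0.084 \cdot 332 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' is evaluated for every donor/acceptor pair, and a bond is called at
#' E < -0.5 kcal/mol.  Residues in runs of i -> i+4 turns of length >= 4 are
#' labelled H; residues in bridge ladders (parallel or antiparallel, ladder
#' length >= 2) are labelled E; everything else is C.  Only H/E membership is
#' consumed downstream (tier-4 constraints), so the full 8-class scheme is
#' deliberately not reproduced.
#'
#' @param s a single-chain [ProteinStructure-class]; residues missing any of
#'   N, CA, C, O are labelled C with a warning.
#' @param model model index used for coordinates.
#' @return character vector of labels in \{H, E, C\}, named by residue
#'   number.
#' @examples
#' table(assignSecondaryStructure(makeHelix(15)))
#' @export
assignSecondaryStructure <- function(s, model = 1L) {
  stopifnot(is(s, "ProteinStructure"))
  keys <- unique(residueKeys(s))
  nres <- length(keys)
  rids <- residueIds(s)
  labels <- rep("C", nres)
  names(labels) <- rids
  if (nres < 5L) return(labels)

  idx <- function(name) atomIndexByResidue(s, name)
  iN <- idx("N"); iCA <- idx("CA"); iC <- idx("C"); iO <- idx("O")
  ok <- !(is.na(iN) | is.na(iCA) | is.na(iC) | is.na(iO))
  if (any(!ok))
    warning(sum(!ok), " residue(s) missing backbone atoms; labelled C")
  x <- coords(s, model)

  hb <- hbondMatrix(x, iN, iCA, iC, iO, ok, s@atoms$resid[iCA])

  # helices: i -> i+4 turn at i iff CO(i) accepts from NH(i+4);
  # consecutive turns at i-1 and i make residues i..i+3 helical
  turn <- rep(FALSE, nres)
  for (i in seq_len(nres - 4L)) turn[i] <- hb[i + 4L, i]  # donor i+4, acceptor i
  for (i in 2:max(2L, nres - 4L))
    if (turn[i - 1L] && turn[i]) labels[i:(i + 3L)] <- "H"

  # bridges (Kabsch-Sander definitions); HB(d, a): NH of d donates to CO of a
  HB <- function(d, a) d >= 1L && d <= nres && a >= 1L && a <= nres && hb[d, a]
  bridge <- matrix(FALSE, nres, nres)
  for (i in 2:(nres - 1L)) for (j in 2:(nres - 1L)) {
    if (abs(i - j) < 3L) next
    par <- (HB(i, j - 1L) && HB(j + 1L, i)) || (HB(j, i - 1L) && HB(i + 1L, j))
    anti <- (HB(i, j) && HB(j, i)) || (HB(i + 1L, j - 1L) && HB(j + 1L, i - 1L))
    if (par || anti) bridge[i, j] <- TRUE
  }
  # ladders: a bridge extended by an adjacent bridge (>= 2 consecutive)
  inLadder <- function(i, j) {
    for (di in c(-1L, 1L)) for (dj in c(-1L, 1L)) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1L && ii <= nres && jj >= 1L && jj <= nres && bridge[ii, jj])
        return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(nres)) for (j in seq_len(nres))
    if (bridge[i, j] && inLadder(i, j) && labels[i] != "H") labels[i] <- "E"
  labels[!ok] <- "C"
  labels
}

# Donor x acceptor hydrogen-bond matrix; hb[d, a] TRUE when the NH of
# residue d donates to the CO of residue a.
hbondMatrix <- function(x, iN, iCA, iC, iO, ok, resid_ca) {
  nres <- length(iN)
  # ideal amide H: 1 A from N along the direction opposite the preceding
  # carbonyl (C=O of residue d-1)
  H <- matrix(NA_real_, nres, 3L)
  for (d in 2:nres) {
    if (!ok[d] || !ok[d - 1L]) next
    v <- x[iC[d - 1L], ] - x[iO[d - 1L], ]
    H[d, ] <- x[iN[d], ] + v / sqrt(sum(v^2))
  }
  hb <- matrix(FALSE, nres, nres)
  q <- 0.084 * 332
  for (d in 2:nres) {
    if (any(is.na(H[d, ])) || resid_ca[d] == "PRO") next
    for (a in seq_len(nres)) {
      if (!ok[a] || abs(d - a) < 2L) next
      rON <- sqrt(sum((x[iO[a], ] - x[iN[d], ])^2))
      if (rON > 5.2) next
      rCH <- sqrt(sum((x[iC[a], ] - H[d, ])^2))
      rOH <- sqrt(sum((x[iO[a], ] - H[d, ])^2))
      rCN <- sqrt(sum((x[iC[a], ] - x[iN[d], ])^2))
      e <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (e < -0.5) hb[d, a] <- TRUE
    }
  }
  hb
}
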