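#' Default parameters of the constraint extractor
#'
#' Fractional bound widths per tier, the tier-5 contact cutoff, the global
#' van der Waals exclusion factor and the clash-rejection factor.  The tier
#' widths implement the qualitative contract that stronger interactions must
#' satisfy tighter separation criteria: covalent bonds (tier 1) get the
#' tightest bounds, long-range contacts (tier 5) the loosest.
#'
#' @return named list of parameters (fractions and Angstrom).
#' @export
constraintParams <- function() {
  list(tol1 = 0.005,      # covalent bonds: d * (1 +/- 0.5%)
       tol2 = 0.015,      # 1-3 pairs + rigid/planar groups: +/- 1.5%
       tol3 = 0.05,       # 1-4 pairs: +/- 5%
       tol4 = 0.10,       # backbone H-bond N...O inside H/E: +/- 10%
       tier5Cutoff = 6.0, # heavy-atom contact cutoff (A)
       tier5LowerFactor = 0.8, tier5UpperFactor = 1.25,
       exclusionFactor = 0.8,  # unconstrained pairs: d >= 0.8 * vdW sum
       clashFactor = 0.5)      # input rejection threshold
}

#' Extract tiered distance constraints from one structure
#'
#' Defines the geometric constraints that the distance-geometry generator
#' later enforces.  Tier 1 covers covalent bonds (residue template +
#' peptide links), tier 2 the 1-3 pairs and rigid/planar groups (aromatic
#' rings, carboxylate/amide planes, guanidinium, the peptide plane), tier 3
#' the 1-4 pairs, tier 4 backbone hydrogen-bond partner N...O pairs inside
#' helix/strand elements, and tier 5 every remaining heavy-atom pair closer
#' than the contact cutoff.  Bounds are the observed distance widened by the
#' tier's fractional tolerance; tier-5 lower bounds are additionally floored
#' at the van der Waals sum (but never above the observed distance, so the
#' generating structure always satisfies its own constraint set).  Pairs not
#' covered by any constraint are subject to a global exclusion floor of
#' \code{exclusionFactor * vdW sum}.
#'
#' @param s sanitized single-model [ProteinStructure-class] (see
#'   [prepareInput()]).
#' @param params parameter list, see [constraintParams()].
#' @return a [ConstraintSet-class].
#' @details Inputs containing a non-bonded pair below
#'   \code{clashFactor * vdW sum} are rejected with a diagnostic.
#' @examples
#' cs <- extractConstraints(makeHelix(8))
#' cs
#' @export
extractConstraints <- function(s, params = constraintParams()) {
  stopifnot(is(s, "ProteinStructure"))
  a <- s@atoms
  x <- coords(s, 1L)
  n <- nrow(a)
  key <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
  dij <- function(i, j) sqrt(rowSums((x[i, , drop = FALSE] -
                                      x[j, , drop = FALSE])^2))

  bonds <- covalentBonds(a, x)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }

  # 1-3: pairs of neighbours of a common atom
  p13 <- do.call(rbind, lapply(seq_len(n), function(k) {
    nb <- adj[[k]]
    if (length(nb) < 2L) return(NULL)
    t(utils::combn(sort(nb), 2L))
  }))
  # 1-4: across each bond
  p14 <- do.call(rbind, lapply(seq_len(nrow(bonds)), function(b) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    ni <- setdiff(adj[[i]], j); nj <- setdiff(adj[[j]], i)
    if (!length(ni) || !length(nj)) return(NULL)
    as.matrix(expand.grid(ni, nj))
  }))
  planar <- planarPairs(a, x)

  # tier-4: backbone H-bond partners inside H/E elements
  p4 <- hbondPairs(s, x)

  taken <- rep(FALSE, n * n)
  out_i <- integer(0); out_j <- integer(0)
  out_lo <- numeric(0); out_up <- numeric(0); out_t <- integer(0)
  addTier <- function(pairs, tier, lo, up) {
    if (is.null(pairs) || !nrow(pairs)) return(invisible())
    i <- pmin(pairs[, 1], pairs[, 2]); j <- pmax(pairs[, 1], pairs[, 2])
    ok <- i != j
    k <- key(i, j)
    ok <- ok & !taken[k] & !duplicated(k)
    if (!any(ok)) return(invisible())
    i <- i[ok]; j <- j[ok]; k <- k[ok]
    taken[k] <<- TRUE
    d <- dij(i, j)
    out_i <<- c(out_i, i); out_j <<- c(out_j, j)
    out_lo <<- c(out_lo, lo(d)); out_up <<- c(out_up, up(d))
    out_t <<- c(out_t, rep(tier, length(i)))
  }
  p <- params
  addTier(bonds, 1L, function(d) d * (1 - p$tol1), function(d) d * (1 + p$tol1))
  addTier(rbind(p13, planar), 2L,
          function(d) d * (1 - p$tol2), function(d) d * (1 + p$tol2))
  addTier(p14, 3L, function(d) d * (1 - p$tol3), function(d) d * (1 + p$tol3))
  addTier(p4, 4L, function(d) d * (1 - p$tol4), function(d) d * (1 + p$tol4))

  # tier 5: remaining heavy-atom pairs below the contact cutoff
  dm <- as.matrix(stats::dist(x))
  close_idx <- which(upper.tri(dm) & dm < p$tier5Cutoff, arr.ind = TRUE)
  if (nrow(close_idx)) {
    i <- close_idx[, 1]; j <- close_idx[, 2]
    keep <- !taken[key(i, j)]
    i <- i[keep]; j <- j[keep]
    if (length(i)) {
      d <- dm[cbind(i, j)]
      vsum <- vdwRadius(a$elesy[i]) + vdwRadius(a$elesy[j])
      clash <- d < p$clashFactor * vsum
      if (any(clash)) {
        w <- which(clash)[1]
        stop(sprintf(
          "clashing input: atoms %d (%s %s%d) and %d (%s %s%d) at %.2f A (< %.2f A)",
          i[w], a$elety[i[w]], a$resid[i[w]], a$resno[i[w]],
          j[w], a$elety[j[w]], a$resid[j[w]], a$resno[j[w]],
          d[w], p$clashFactor * vsum[w]))
      }
      lo <- pmin(d, pmax(vsum, d * p$tier5LowerFactor))
      taken[key(i, j)] <- TRUE
      out_i <- c(out_i, i); out_j <- c(out_j, j)
      out_lo <- c(out_lo, lo); out_up <- c(out_up, d * p$tier5UpperFactor)
      out_t <- c(out_t, rep(5L, length(i)))
    }
  }

  radii <- .VDW_RADII
  extra <- setdiff(unique(a$elesy), names(radii))
  if (length(extra)) {
    radii <- c(radii, stats::setNames(rep(.VDW_DEFAULT, length(extra)), extra))
  }
  cs <- new("ConstraintSet",
            constraints = data.frame(i = out_i, j = out_j, lower = out_lo,
                                     upper = out_up, tier = out_t),
            radii = radii, nAtoms = as.integer(n))
  validObject(cs)
  cs
}

# Covalent bond index pairs: residue templates (backbone + side chain),
# distance-based fallback for non-template residues, peptide links.
covalentBonds <- function(a, x) {
  n <- nrow(a)
  keys <- residueKeys(a)
  ukeys <- unique(keys)
  res_idx <- split(seq_len(n), factor(keys, levels = ukeys))
  pairs <- list()
  addByName <- function(idx, n1, n2) {
    i <- idx[match(n1, a$elety[idx])]; j <- idx[match(n2, a$elety[idx])]
    if (!is.na(i) && !is.na(j)) pairs[[length(pairs) + 1L]] <<- c(i, j)
  }
  for (r in seq_along(res_idx)) {
    idx <- res_idx[[r]]
    resid <- a$resid[idx[1]]
    if (resid %in% names(.SIDECHAIN_BONDS)) {
      addByName(idx, "N", "CA"); addByName(idx, "CA", "C")
      addByName(idx, "C", "O"); addByName(idx, "C", "OXT")
      for (b in .SIDECHAIN_BONDS[[resid]]) addByName(idx, b[1], b[2])
    } else {
      # unknown residue type: bond by distance
      if (length(idx) > 1L) {
        cmb <- t(utils::combn(idx, 2L))
        d <- sqrt(rowSums((x[cmb[, 1], , drop = FALSE] -
                           x[cmb[, 2], , drop = FALSE])^2))
        cut <- ifelse(a$elesy[cmb[, 1]] == "S" | a$elesy[cmb[, 2]] == "S",
                      2.2, 1.9)
        for (w in which(d < cut)) pairs[[length(pairs) + 1L]] <- cmb[w, ]
      }
    }
    # peptide link to the next residue in file order (same chain)
    if (r < length(res_idx)) {
      nxt <- res_idx[[r + 1L]]
      if (a$chain[idx[1]] == a$chain[nxt[1]]) {
        ci <- idx[match("C", a$elety[idx])]
        nj <- nxt[match("N", a$elety[nxt])]
        if (!is.na(ci) && !is.na(nj) &&
            sqrt(sum((x[ci, ] - x[nj, ])^2)) < 1.8)
          pairs[[length(pairs) + 1L]] <- c(ci, nj)
      }
    }
  }
  if (!length(pairs)) return(matrix(integer(0), ncol = 2L))
  unique(t(vapply(pairs, function(p) c(min(p), max(p)), integer(2L))))
}

# All atom pairs inside rigid/planar groups: side-chain groups by template
# plus the peptide plane CA(i), C(i), O(i), N(i+1), CA(i+1) where the
# peptide bond actually exists.
planarPairs <- function(a, x) {
  n <- nrow(a)
  keys <- residueKeys(a)
  ukeys <- unique(keys)
  res_idx <- split(seq_len(n), factor(keys, levels = ukeys))
  pairs <- list()
  grab <- function(idx, names) {
    i <- idx[match(names, a$elety[idx])]
    i[!is.na(i)]
  }
  for (r in seq_along(res_idx)) {
    idx <- res_idx[[r]]
    resid <- a$resid[idx[1]]
    for (g in .PLANAR_GROUPS[[resid]]) {
      m <- grab(idx, g)
      if (length(m) > 1L)
        pairs[[length(pairs) + 1L]] <- t(utils::combn(m, 2L))
    }
    if (r < length(res_idx)) {
      nxt <- res_idx[[r + 1L]]
      ci <- idx[match("C", a$elety[idx])]
      nj <- nxt[match("N", a$elety[nxt])]
      linked <- a$chain[idx[1]] == a$chain[nxt[1]] &&
        !is.na(ci) && !is.na(nj) && sqrt(sum((x[ci, ] - x[nj, ])^2)) < 1.8
      if (linked) {
        m <- c(grab(idx, c("CA", "C", "O")), grab(nxt, c("N", "CA")))
        if (length(m) > 1L)
          pairs[[length(pairs) + 1L]] <- t(utils::combn(m, 2L))
      }
    }
  }
  if (!length(pairs)) return(NULL)
  do.call(rbind, pairs)
}

# Backbone H-bond partner heavy-atom pairs (donor N, acceptor O) where both
# residues sit inside helix or strand elements.
hbondPairs <- function(s, x) {
  labels <- tryCatch(suppressWarnings(assignSecondaryStructure(s)),
                     error = function(e) NULL)
  if (is.null(labels)) return(NULL)
  iN <- atomIndexByResidue(s, "N"); iCA <- atomIndexByResidue(s, "CA")
  iC <- atomIndexByResidue(s, "C"); iO <- atomIndexByResidue(s, "O")
  ok <- !(is.na(iN) | is.na(iCA) | is.na(iC) | is.na(iO))
  if (sum(ok) < 5L) return(NULL)
  hb <- hbondMatrix(x, iN, iCA, iC, iO, ok, s@atoms$resid[iCA])
  w <- which(hb, arr.ind = TRUE)
  if (!nrow(w)) return(NULL)
  keep <- labels[w[, 1]] %in% c("H", "E") & labels[w[, 2]] %in% c("H", "E")
  w <- w[keep, , drop = FALSE]
  if (!nrow(w)) return(NULL)
  cbind(iN[w[, 1]], iO[w[, 2]])
}

#' Worst violation of a constraint set by a coordinate set
#'
#' The maximum, over all constraints and all excluded (unconstrained)
#' pairs, of the distance by which a coordinate set breaks its bounds.
#' Zero means every bound is satisfied.
#'
#' @param cs a [ConstraintSet-class].
#' @param xyz nAtoms x 3 coordinate matrix.
#' @param elements element symbols per atom (for the exclusion floor);
#'   taken from \code{cs@radii} names via this vector.
#' @param exclusionFactor exclusion floor factor (default 0.8).
#' @return numeric scalar (A).
#' @export
constraintViolation <- function(cs, xyz, elements,
                                exclusionFactor = 0.8) {
  stopifnot(is(cs, "ConstraintSet"), nrow(xyz) == cs@nAtoms)
  co <- cs@constraints
  d <- sqrt(rowSums((xyz[co$i, , drop = FALSE] -
                     xyz[co$j, , drop = FALSE])^2))
  v <- pmax(co$lower - d, d - co$upper, 0)
  # exclusion over unconstrained pairs
  n <- cs@nAtoms
  dm <- as.matrix(stats::dist(xyz))
  r <- cs@radii[elements]; r[is.na(r)] <- .VDW_DEFAULT
  floorm <- exclusionFactor * outer(r, r, "+")
  viol <- floorm - dm
  diag(viol) <- 0
  kc <- (co$i - 1) * n + co$j
  viol[kc] <- 0; viol[(co$j - 1) * n + co$i] <- 0
  max(v, viol, 0)
}
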