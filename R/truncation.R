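#' Progressive truncation ladder
#'
#' The 20 retained-fraction levels k/20, k = 20..1 (100%, 95%, ..., 5%),
#' converted to residue counts by \code{floor(nResidues * k/20)} and
#' clamped to at least 1 residue.  Levels whose residue counts coincide
#' (small proteins) are merged, keeping the largest fraction.  Flooring (not
#' rounding) is used: it is the unique choice consistent with the ladder of
#' a 259-residue chain containing 25, 38, 51, 64, 77, 90, ... residues.
#'
#' @param nResidues chain length (>= 1).
#' @param nLevels number of levels (default 20).
#' @return data.frame with columns \code{fraction}, \code{percent} and
#'   \code{nKeep}, largest level first.
#' @examples
#' truncationLadder(100)$nKeep   # 100, 95, ..., 5
#' @export
truncationLadder <- function(nResidues, nLevels = 20L) {
  stopifnot(nResidues >= 1L, nLevels >= 1L)
  k <- seq(nLevels, 1L)
  frac <- k / nLevels
  nKeep <- pmax(1L, as.integer(floor(nResidues * frac)))
  keep <- !duplicated(nKeep)
  data.frame(fraction = frac[keep], percent = round(100 * frac[keep]),
             nKeep = nKeep[keep])
}

#' Select the residues retained at one truncation level
#'
#' Keeps the \code{nKeep} residues with the LOWEST scores: residues are
#' removed in decreasing score order, so high-variance (or generally
#' high-score) residues go first.  Ties are broken by ascending residue
#' number.  Only the ranks of the scores matter: scaling by a positive
#' constant or adding a constant does not change the selection.
#'
#' @param profile data.frame whose first column is the residue number and
#'   second the score (e.g. a [varianceProfile()]), or a numeric vector
#'   named by residue number.
#' @param nKeep number of residues to retain.
#' @return sorted integer vector of retained residue numbers.
#' @examples
#' selectResidues(data.frame(resno = 1:3, s = c(3, 1, 2)), 2)  # 2 3
#' @export
selectResidues <- function(profile, nKeep) {
  if (is.data.frame(profile)) {
    resno <- as.integer(profile[[1]]); score <- as.numeric(profile[[2]])
  } else {
    resno <- as.integer(names(profile)); score <- as.numeric(profile)
  }
  stopifnot(!anyNA(resno), !anyNA(score))
  if (nKeep > length(resno))
    stop("nKeep (", nKeep, ") exceeds available residues (", length(resno), ")")
  ord <- order(score, resno)
  sort(resno[ord[seq_len(nKeep)]])
}

#' Apply a side-chain treatment to a model
#'
#' \code{"allatom"} leaves the model unchanged; \code{"polyala"} retains
#' only N, CA, C, O, CB and rewrites residue names to ALA (glycine keeps
#' its name and has no CB); \code{"reliable"} keeps side chains only for
#' residue types in \code{reliableSet} — broadly those with few well
#' occupied rotamers, whose conformation is most likely maintained in a
#' homologue — and strips all others to polyalanine atoms.
#'
#' @param model a [ProteinStructure-class].
#' @param mode one of \code{"allatom"}, \code{"reliable"},
#'   \code{"polyala"}.
#' @param reliableSet residue types whose side chains survive
#'   \code{"reliable"} mode.
#' @return the processed [ProteinStructure-class].
#' @export
applySideChains <- function(model, mode = c("allatom", "reliable", "polyala"),
                            reliableSet = .RELIABLE_SIDECHAINS) {
  mode <- match.arg(mode)
  if (mode == "allatom") return(model)
  a <- model@atoms
  strip <- if (mode == "polyala") rep(TRUE, nrow(a)) else
    !(a$resid %in% reliableSet)
  keep <- !strip | a$elety %in% .POLYALA_ATOMS
  out <- subsetAtoms(model, keep)
  a <- out@atoms
  renm <- if (mode == "polyala") rep(TRUE, nrow(a)) else
    !(a$resid %in% reliableSet)
  renm <- renm & a$resid != "GLY"
  out@atoms$resid[renm] <- "ALA"
  out
}

#' Build the full ensemble-mode search-model pool
#'
#' For each used cluster: the per-residue variance profile of the cluster's
#' members drives a 20-level truncation ladder; each level is combined with
#' each subclustering radius and each side-chain treatment, one search
#' model per combination.  Subcluster members are superposed onto the
#' centroid before assembly.  No deduplication is applied by default, so
#' the pool size obeys
#' \code{|levels| * |radii| * |modes| * |clusters used|}
#' (180 per cluster at the defaults, 540 for three clusters); identical
#' models that arise when different radii capture the same member set can
#' be removed with \code{dedupe = TRUE}.
#'
#' @param e a [ConformationEnsemble-class].
#' @param clusters a [ClusterSet-class] from [clusterEnsemble()].
#' @param nClustersUsed clusters to process (1 or 3 typically; capped at
#'   the number available).
#' @param radii subclustering radii in A (default \code{c(1, 2, 3)}).
#' @param modes side-chain treatments.
#' @param cap subcluster size cap (default 30).
#' @param nLevels truncation levels (default 20).
#' @param reliableSet see [applySideChains()].
#' @param dedupe drop models identical in member set, residues and mode.
#' @return list of [SearchModel-class] objects.
#' @examples
#' e <- makePerturbedEnsemble(makeHelix(20), 10, 0.3, seed = 1)
#' cl <- clusterEnsemble(e)
#' pool <- buildSearchModels(e, cl, nClustersUsed = 1)
#' length(pool)  # 180
#' @export
buildSearchModels <- function(e, clusters, nClustersUsed = 1L,
                              radii = c(1, 2, 3),
                              modes = c("allatom", "reliable", "polyala"),
                              cap = 30L, nLevels = 20L,
                              reliableSet = .RELIABLE_SIDECHAINS,
                              dedupe = FALSE) {
  stopifnot(is(e, "ConformationEnsemble"), is(clusters, "ClusterSet"))
  nUse <- min(nClustersUsed, length(clusters@members))
  pool <- list()
  seen <- character(0)
  for (k in seq_len(nUse)) {
    mem <- clusters@members[[k]]
    cen <- clusters@centroids[k]
    vp <- if (length(mem) >= 2L) varianceProfile(e, mem) else
      data.frame(resno = residueIds(e), variance = 0)
    ladder <- truncationLadder(nResidues(e), nLevels)
    for (li in seq_len(nrow(ladder))) {
      kept <- selectResidues(vp, ladder$nKeep[li])
      for (r in radii) {
        sub <- subcluster(e, mem, cen, r, cap)
        base <- assembleEnsembleModel(e, sub, cen, kept)
        for (mode in modes) {
          sm <- applySideChains(base, mode, reliableSet)
          label <- sprintf("c%d_t%d_r%g_%s", k, ladder$percent[li], r, mode)
          if (dedupe) {
            sig <- paste(mode, paste(sub, collapse = ","),
                         paste(kept, collapse = ","))
            if (sig %in% seen) next
            seen <- c(seen, sig)
          }
          pool[[length(pool) + 1L]] <- new("SearchModel",
            model = sm, nResidues = length(kept), sideChainMode = mode,
            subclusterRadius = as.numeric(r), clusterIndex = as.integer(k),
            scoreColumn = "variance", label = label)
        }
      }
    }
  }
  pool
}

# Truncate the ensemble to kept residues and superpose the selected members
# onto the centroid (Calpha fit over the kept residues).
assembleEnsembleModel <- function(e, memberIdx, centroid, keptResnos) {
  sub <- subsetResidues(e, keptResnos)
  caIdx <- atomIndexByResidue(sub, "CA")
  caIdx <- caIdx[!is.na(caIdx)]
  refCA <- coords(sub, centroid)[caIdx, , drop = FALSE]
  # subsetResidues keeps all models; pick and align the selected ones
  arr <- array(NA_real_, dim = c(nAtoms(sub), 3L, length(memberIdx)))
  for (t in seq_along(memberIdx)) {
    xm <- coords(sub, memberIdx[t])
    if (nrow(refCA) >= 3L) {
      sp <- superpose(refCA, xm[caIdx, , drop = FALSE])
      arr[, , t] <- applySuperposition(xm, sp)
    } else {
      # 1-2 residue levels: rotation is underdetermined, align centroids
      shift <- colMeans(refCA) - colMeans(xm[caIdx, , drop = FALSE])
      arr[, , t] <- sweep(xm, 2L, shift, "+")
    }
  }
  newStructure(sub@atoms, arr)
}

#' Manifest of a search-model pool
#'
#' @param pool list of [SearchModel-class] objects.
#' @param files optional file paths written for each model.
#' @return data.frame (one row per model): label, cluster, radius, mode,
#'   score column, residue and member counts.
#' @export
searchModelManifest <- function(pool, files = NULL) {
  df <- do.call(rbind, lapply(pool, function(sm) data.frame(
    label = sm@label, cluster = sm@clusterIndex,
    radius = sm@subclusterRadius, mode = sm@sideChainMode,
    score_column = sm@scoreColumn, n_residues = sm@nResidues,
    n_members = nModels(sm@model), stringsAsFactors = FALSE)))
  if (!is.null(files)) df$file <- files
  df
}
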