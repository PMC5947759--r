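#' Cluster ensemble members by pairwise Calpha RMSD
#'
#' Greedy neighbour-count clustering on the pairwise Calpha-RMSD matrix (in
#' the style of decoy-clustering programs): the member with the most
#' neighbours within the cutoff seeds cluster 1 and takes its neighbours
#' with it; the procedure repeats on the remaining members for clusters
#' 2, 3, ...  The cutoff is auto-tuned from an initial 1.5 A inside
#' [0.5, 8.0] A (bisection) until cluster 1 holds between 15% and 85% of
#' the members, so the top cluster is neither trivial nor all-encompassing.
#'
#' @param e a [ConformationEnsemble-class].
#' @param cutoff initial RMSD cutoff (A).
#' @param band fraction band for cluster 1 (default \code{c(0.15, 0.85)}).
#' @param bounds cutoff search interval (A).
#' @param dm optional pre-computed pairwise RMSD matrix.
#' @return a [ClusterSet-class]; clusters ordered by decreasing size, ties
#'   broken by lowest centroid index.  An ensemble of < 2 members yields a
#'   single (singleton) cluster.
#' @examples
#' e <- makePerturbedEnsemble(makeHelix(10), 8, 0.2, seed = 1)
#' clusterEnsemble(e)
#' @export
clusterEnsemble <- function(e, cutoff = 1.5, band = c(0.15, 0.85),
                            bounds = c(0.5, 8.0), dm = NULL) {
  m <- nModels(e)
  if (m < 2L)
    return(new("ClusterSet", members = list(1L), centroids = 1L,
               cutoff = cutoff))
  if (is.null(dm)) dm <- pairwiseRmsd(e)

  frac1 <- function(cut) max(rowSums(dm <= cut)) / m  # incl. self
  cut <- min(max(cutoff, bounds[1]), bounds[2])
  f <- frac1(cut)
  if (f < band[1] || f > band[2]) {
    lo <- bounds[1]; hi <- bounds[2]
    for (it in 1:40) {
      if (f < band[1]) lo <- cut else hi <- cut
      cut <- (lo + hi) / 2
      f <- frac1(cut)
      if (f >= band[1] && f <= band[2]) break
    }
  }

  remaining <- seq_len(m)
  members <- list(); centroids <- integer(0)
  while (length(remaining)) {
    counts <- rowSums(dm[remaining, remaining, drop = FALSE] <= cut)
    seed_i <- remaining[which.max(counts)]   # ties -> lowest index
    cl <- remaining[dm[seed_i, remaining] <= cut]
    members[[length(members) + 1L]] <- sort(cl)
    centroids <- c(centroids, seed_i)
    remaining <- setdiff(remaining, cl)
  }
  ord <- order(-vapply(members, length, integer(1)), centroids)
  new("ClusterSet", members = members[ord], centroids = centroids[ord],
      cutoff = cut)
}

#' Select the subcluster of members within a radius of the centroid
#'
#' Members whose Calpha RMSD to the centroid (after superposition) is at
#' most \code{radius}, ranked by that RMSD and truncated to \code{cap}.
#' The centroid itself is always included (RMSD 0, first rank).
#'
#' @param e a [ConformationEnsemble-class].
#' @param members integer vector of candidate member indices.
#' @param centroid centroid member index.
#' @param radius subclustering radius (A).
#' @param cap maximum number of members returned (default 30).
#' @return integer vector of member indices, nearest first.
#' @export
subcluster <- function(e, members, centroid, radius, cap = 30L) {
  stopifnot(centroid %in% members)
  ref <- caCoords(e, centroid)
  r <- vapply(members, function(k) {
    if (k == centroid) return(0)
    superpose(ref, caCoords(e, k))$rmsd
  }, numeric(1))
  ord <- order(r, members)
  sel <- ord[r[ord] <= radius]
  members[utils::head(sel, cap)]
}
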