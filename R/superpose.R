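#' Weighted least-squares superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the weighted
#' RMSD of point set \code{b} onto point set \code{a}:
#' \deqn{\min_{R,t} \sum_i w_i \| a_i - (R b_i + t) \|^2 .}
#' Collinear (rank-deficient) point sets are flagged and fitted by
#' translation only.
#'
#' @param a,b n x 3 coordinate matrices, n >= 3.
#' @param weights non-negative weights, not all zero (default: uniform).
#' @return list with \code{rotation} (3 x 3, det = +1),
#'   \code{translation} (length 3), \code{rmsd} (weighted, A) and
#'   \code{degenerate} (logical).
#' @examples
#' a <- matrix(rnorm(30), 10)
#' sp <- superpose(a, a + 5)
#' sp$rmsd
#' @export
superpose <- function(a, b, weights = NULL) {
  stopifnot(is.matrix(a), is.matrix(b), ncol(a) == 3L, ncol(b) == 3L,
            nrow(a) == nrow(b), nrow(a) >= 3L)
  n <- nrow(a)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), any(weights > 0))
  w <- weights / sum(weights)
  ca <- colSums(a * w); cb <- colSums(b * w)
  A0 <- sweep(a, 2L, ca); B0 <- sweep(b, 2L, cb)
  C <- crossprod(B0 * w, A0)            # sum_i w_i b0_i a0_i^T
  sv <- svd(C)
  degenerate <- sv$d[2] < 1e-10 * max(sv$d[1], 1e-30)
  if (degenerate) {
    R <- diag(3)
  } else {
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  t_vec <- ca - as.vector(R %*% cb)
  resid <- A0 - B0 %*% t(R)
  rmsd <- sqrt(sum(w * rowSums(resid^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd,
       degenerate = degenerate)
}

#' Apply a superposition to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param sp result of [superpose()].
#' @return transformed n x 3 matrix (\code{R xyz + t}).
#' @export
applySuperposition <- function(xyz, sp) {
  sweep(xyz %*% t(sp$rotation), 2L, -sp$translation)
}

#' Pairwise Calpha-RMSD matrix of an ensemble
#'
#' Least-squares RMSD between every pair of members after optimal
#' superposition (computed in compiled code).  The matrix is symmetric with
#' a zero diagonal.
#'
#' @param e a [ConformationEnsemble-class] (or any multi-model
#'   [ProteinStructure-class]).
#' @return m x m numeric matrix (A).
#' @export
pairwiseRmsd <- function(e) {
  m <- nModels(e)
  idx <- atomIndexByResidue(e, "CA")
  idx <- idx[!is.na(idx)]
  nca <- length(idx)
  stopifnot(nca >= 3L)
  flat <- vapply(seq_len(m), function(k) as.vector(coords(e, k)[idx, ]),
                 numeric(nca * 3L))
  .pairwise_rmsd(matrix(flat, ncol = m), nca)
}
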