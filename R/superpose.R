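#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` (det +1) and translation `t` minimising the
#' root-mean-square deviation between corresponding points `P[i,]` and
#' `R %*% Q[i,] + t`, via singular value decomposition of the
#' cross-covariance matrix.
#'
#' @param P n x 3 matrix of reference points (A), n >= 3.
#' @param Q n x 3 matrix of moving points, row i corresponding to `P[i,]`.
#' @return list with `rmsd` (A), `rotation` (3 x 3, det +1), `translation`
#'   (length 3), and `degenerate` (TRUE when the point sets are collinear or
#'   coincident, in which case the best proper rotation is still returned).
#' @export
superpose_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L)
    stop("P and Q must be n x 3 matrices with equal n")
  n <- nrow(P)
  if (n < 3L) stop("at least 3 point pairs are required")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Qc, Pc)              # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  # degenerate when rank < 2 (collinear/coincident): rotation about the
  # line is unconstrained but the returned proper rotation is still optimal
  degenerate <- sv$d[2] < 1e-10 * max(sv$d[1], 1e-12)
  Qr <- Qc %*% t(R)
  rmsd <- sqrt(sum((Pc - Qr)^2) / n)
  t_vec <- cp - as.vector(R %*% cq)
  list(rmsd = rmsd, rotation = R, translation = t_vec,
       degenerate = degenerate)
}

#' Generate a random proper rotation matrix
#'
#' Uniform over SO(3) (via QR decomposition of a Gaussian matrix with sign
#' correction). Uses the current RNG stream.
#'
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Qm <- qr.Q(qr_)
  Qm <- Qm %*% diag(sign(diag(qr.R(qr_))))
  if (det(Qm) < 0) Qm[, 1] <- -Qm[, 1]
  Qm
}
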