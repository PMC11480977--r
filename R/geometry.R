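# Rigid-body geometry: quaternions, rotations, least-squares superposition.

#' Normalize a quaternion
#' @param q numeric length-4 vector (w, x, y, z).
#' @return unit quaternion.
#' @keywords internal
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-300) stop("cannot normalize a zero quaternion")
  q / n
}

#' Quaternion to rotation matrix
#'
#' Converts a unit quaternion (w, x, y, z) to a 3x3 proper rotation matrix
#' acting on row vectors as \code{coords \%*\% t(R)} or column vectors as
#' \code{R \%*\% v}.
#' @param q unit quaternion.
#' @return 3x3 rotation matrix.
#' @keywords internal
quat_to_mat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Uniform random rotation (as quaternion)
#'
#' Four independent normal deviates normalized to the unit 3-sphere give a
#' rotation uniform over SO(3).
#' @return unit quaternion.
#' @keywords internal
random_quat <- function() quat_normalize(stats::rnorm(4))

#' Rotation about an arbitrary axis
#' @param axis 3-vector (need not be unit).
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotmat_axis_angle <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s1 <- sin(angle); t1 <- 1 - c1
  x <- a[1]; y <- a[2]; z <- a[3]
  matrix(c(
    t1 * x * x + c1,     t1 * x * y - s1 * z, t1 * x * z + s1 * y,
    t1 * x * y + s1 * z, t1 * y * y + c1,     t1 * y * z - s1 * x,
    t1 * x * z - s1 * y, t1 * y * z + s1 * x, t1 * z * z + c1
  ), nrow = 3, byrow = TRUE)
}

# Exponential-map rotation from a 3-vector (axis * angle); identity at 0.
rotmat_expmap <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  rotmat_axis_angle(v, th)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param R 3x3 rotation.
#' @param t length-3 translation.
#' @return transformed n x 3 matrix.
#' @keywords internal
apply_transform <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}

# Rotate coords about a pivot point then translate.
rotate_about <- function(xyz, R, pivot, shift = c(0, 0, 0)) {
  ctr <- matrix(pivot, nrow(xyz), 3, byrow = TRUE)
  (xyz - ctr) %*% t(R) + ctr + matrix(shift, nrow(xyz), 3, byrow = TRUE)
}

# Squared cross-distance matrix between two coordinate sets (nA x nB).
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired atom coordinates, via SVD of the cross-covariance matrix with the
#' usual determinant correction so that reflections are never returned.
#'
#' @param mobile n x 3 matrix of coordinates to be fitted.
#' @param reference n x 3 matrix of target coordinates, row-paired with
#'   \code{mobile}.
#' @param fit_idx optional integer vector: fit on this subset of rows; the
#'   returned transform still applies to the whole mobile set. Default: all.
#' @return list with \code{R} (3x3 rotation), \code{t} (translation such that
#'   \code{mobile \%*\% t(R) + t} superposes onto the reference), and
#'   \code{rmsd}, the fitted RMSD over the fit selection.
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' R <- quat_to_mat(c(0.7, 0.3, 0.5, 0.4))
#' y <- x %*% t(R)
#' kabsch_superpose(x, y)$rmsd  # ~0
#' @export
kabsch_superpose <- function(mobile, reference, fit_idx = NULL) {
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(mobile))
  X <- mobile[fit_idx, , drop = FALSE]
  Y <- reference[fit_idx, , drop = FALSE]
  if (nrow(X) != nrow(Y)) stop("paired coordinate sets differ in length")
  if (nrow(X) < 3) stop("need at least 3 paired atoms for superposition")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  # conditioning: collinear selections have a rank-deficient covariance
  if (qr(Xc)$rank < 2 || qr(Yc)$rank < 2)
    stop("degenerate (collinear) fit selection")
  C <- t(Xc) %*% Yc
  s <- svd(C)
  d <- sign(det(s$u) * det(s$v))
  # row-vector convention: fitted = X %*% Rm, so R = t(Rm)
  Rm <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Xc %*% Rm
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  R <- t(Rm)
  tvec <- cy - as.vector(cx %*% Rm)
  list(R = R, t = tvec, rmsd = rmsd)
}

# Plain RMSD between paired coordinate rows (no fitting).
coord_rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))
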