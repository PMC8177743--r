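## Unit-quaternion parameterization of SO(3).
## Quaternions are length-4 numeric vectors (w, x, y, z), Hamilton convention;
## q and -q encode the same rotation.

#' Convert a unit quaternion to a rotation matrix
#'
#' Uses the Hamilton convention with scalar part first, so
#' \code{quaternion_to_matrix(c(1, 0, 0, 0))} is the identity. \code{q} and
#' \code{-q} map to the same matrix.
#'
#' @param q Numeric length-4 vector \code{(w, x, y, z)}; renormalized if its
#'   norm deviates from 1 by less than \code{tol}, rejected otherwise.
#' @param tol Tolerance on \code{abs(norm(q) - 1)} before renormalization.
#' @return A 3x3 rotation matrix (orthogonal, determinant +1).
#' @export
quaternion_to_matrix <- function(q, tol = 1e-6) {
  nq <- sqrt(sum(q^2))
  if (!is.finite(nq) || nq < 1e-12)
    stop("quaternion has (near-)zero norm")
  if (abs(nq - 1) > tol)
    stop("quaternion norm deviates from 1 by more than tol")
  q <- q / nq
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Draw quaternions uniformly on the 3-sphere
#'
#' Normalized 4D standard Gaussians; the induced rotations are Haar-uniform
#' over SO(3).
#'
#' @param n Number of quaternions.
#' @return An \code{n x 4} matrix of unit quaternions.
#' @export
random_quaternion <- function(n = 1) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

#' Frobenius distance between two rotation matrices
#'
#' \code{norm(Ra - Rb, "F")}, bounded by \code{2 * sqrt(2)}; equals
#' \code{sqrt(6 - 2 * tr(t(Ra) %*% Rb))} for rotations.
#'
#' @param Ra,Rb 3x3 rotation matrices.
#' @return Nonnegative scalar.
#' @export
rotation_distance <- function(Ra, Rb) {
  sqrt(sum((Ra - Rb)^2))
}

#' Geodesic angle between two rotations
#'
#' The angle (radians, in \code{[0, pi]}) of the relative rotation
#' \code{t(Ra) %*% Rb}.
#'
#' @param Ra,Rb 3x3 rotation matrices.
#' @return Angle in radians.
#' @export
rotation_angle <- function(Ra, Rb = diag(3)) {
  ctheta <- (sum(diag(crossprod(Ra, Rb))) - 1) / 2
  acos(min(1, max(-1, ctheta)))
}

## internal: is M a proper rotation?
is_rotation <- function(M, tol = 1e-8) {
  is.matrix(M) && all(dim(M) == 3) &&
    max(abs(crossprod(M) - diag(3))) < tol && abs(det(M) - 1) < tol
}
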