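# Small rotation toolbox for rigid-body poses.  Rotations are plain 3x3
# matrices; incremental updates go through the Rodrigues exponential map so the
# solver can work with a minimal 3-parameter rotation increment.

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @param v numeric length-3 vector
#' @return 3x3 matrix \code{S} with \code{S \%*\% x == v x x} (cross product)
#' @keywords internal
skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Rodrigues exponential map: rotation vector to rotation matrix
#'
#' @param w numeric length-3 rotation vector (axis * angle, radians)
#' @return 3x3 proper rotation matrix
#' @export
rot_exp <- function(w) {
  stopifnot(length(w) == 3, all(is.finite(w)))
  th <- sqrt(sum(w^2))
  if (th < 1e-12) {
    # second-order series keeps the map smooth near the identity
    S <- skew3(w)
    return(diag(3) + S + 0.5 * S %*% S)
  }
  S <- skew3(w / th)
  diag(3) + sin(th) * S + (1 - cos(th)) * S %*% S
}

#' Logarithm map: rotation matrix to rotation vector
#' @param R 3x3 proper rotation matrix
#' @return numeric length-3 rotation vector (radians)
#' @export
rot_log <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-10) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  ax * th
}

#' Elementary rotation about a coordinate axis
#' @param angle_deg angle in degrees
#' @param axis one of "x", "y", "z"
#' @return 3x3 rotation matrix
#' @export
rot_axis <- function(angle_deg, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  e <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  rot_exp(e * a)
}

#' Check that a matrix is a proper rotation
#' @param R matrix to test
#' @param tol orthonormality tolerance
#' @return logical
#' @export
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}
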