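#' Quaternion utilities
#'
#' Orientations of rigid molecules are unit quaternions `c(w, x, y, z)`.
#' These helpers are deliberately small and allocation-light; the compiled
#' engine carries its own copies of the same formulas.
#'
#' @name quaternion
#' @keywords internal
NULL

#' Normalize a quaternion to unit length
#' @param q numeric length-4 `c(w, x, y, z)`.
#' @return unit quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n <= 0 || !is.finite(n)) stop("cannot normalize zero or non-finite quaternion")
  q / n
}

#' Quaternion product (Hamilton convention)
#' @param a,b quaternions `c(w, x, y, z)`; result rotates by `b` then `a`.
#' @return quaternion `a * b`.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion from rotation axis and angle
#' @param axis numeric length-3, need not be unit.
#' @param angle rotation angle in radians.
#' @return unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis * axis))
  if (n <= 0) stop("rotation axis must be non-zero")
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Rotation matrix of a unit quaternion
#' @param q unit quaternion `c(w, x, y, z)`.
#' @return 3x3 rotation matrix (world = R %*% body).
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix
#'
#' Shepperd's method; stable for all proper rotations.
#' @param R 3x3 rotation matrix.
#' @return unit quaternion.
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

#' Rotate vectors by a quaternion
#' @param q unit quaternion.
#' @param v numeric length-3 vector or an n x 3 matrix of row vectors.
#' @return rotated vector(s), same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  R <- quat_to_matrix(q)
  if (is.matrix(v)) t(R %*% t(v)) else as.numeric(R %*% v)
}

#' Uniform random unit quaternion
#' @param n number of quaternions.
#' @return n x 4 matrix of unit quaternions (uses the R RNG stream).
#' @export
random_quaternion <- function(n = 1) {
  m <- matrix(stats::rnorm(4 * n), ncol = 4)
  m / sqrt(rowSums(m^2))
}
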