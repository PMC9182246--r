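# Quaternion algebra used throughout the package.
#
# Quaternions are numeric vectors c(w, x, y, z) (scalar first) or N x 4
# matrices of per-sample quaternions. All rotation quaternions are kept at
# unit norm; quat_rotate() applies the rotation q * v * q^-1, i.e. rotates a
# body-frame vector into the frame the quaternion maps to.

quat <- function(w, x, y, z) c(w, x, y, z)

#' Quaternion utilities
#'
#' Minimal scalar-first quaternion algebra (`c(w, x, y, z)`; N x 4 matrices
#' for per-sample series) used for all rotations in the package: identity,
#' Hamilton product, conjugate, vector rotation, axis-angle / rotation-vector
#' construction, elementary axis rotations, the shortest rotation between two
#' vectors, the heading (yaw) of a rotation, and the row-wise cross product.
#'
#' @param p,q Quaternions (length 4, or N x 4 matrices).
#' @param v A 3-vector or N x 3 matrix of vectors.
#' @param axis Rotation axis (3-vector, any norm).
#' @param angle Rotation angle, rad.
#' @param rv Rotation vector(s): axis scaled by angle, rad.
#' @param u Source vector for the shortest rotation.
#' @param a,b 3-vectors or N x 3 matrices.
#' @return Quaternions, rotated vectors, or scalars as appropriate.
#' @name quaternions
NULL

#' @rdname quaternions
#' @export
quat_identity <- function() c(1, 0, 0, 0)

quat_norm <- function(q) {
  if (is.matrix(q)) sqrt(rowSums(q^2)) else sqrt(sum(q^2))
}

quat_normalize <- function(q) {
  if (is.matrix(q)) q / quat_norm(q) else q / sqrt(sum(q^2))
}

#' @rdname quaternions
#' @export
quat_conj <- function(q) {
  if (is.matrix(q)) {
    q[, 2:4] <- -q[, 2:4]
    q
  } else {
    c(q[1], -q[2:4])
  }
}

as_quat_matrix <- function(q, n) {
  if (is.matrix(q)) q else matrix(q, nrow = n, ncol = 4, byrow = TRUE)
}

# Hamilton product; both arguments may be length-4 vectors or N x 4 matrices.
#' @rdname quaternions
#' @export
quat_mul <- function(p, q) {
  vec <- !is.matrix(p) && !is.matrix(q)
  n <- max(if (is.matrix(p)) nrow(p) else 1L, if (is.matrix(q)) nrow(q) else 1L)
  p <- as_quat_matrix(p, n)
  q <- as_quat_matrix(q, n)
  out <- cbind(
    p[, 1] * q[, 1] - p[, 2] * q[, 2] - p[, 3] * q[, 3] - p[, 4] * q[, 4],
    p[, 1] * q[, 2] + p[, 2] * q[, 1] + p[, 3] * q[, 4] - p[, 4] * q[, 3],
    p[, 1] * q[, 3] - p[, 2] * q[, 4] + p[, 3] * q[, 1] + p[, 4] * q[, 2],
    p[, 1] * q[, 4] + p[, 2] * q[, 3] - p[, 3] * q[, 2] + p[, 4] * q[, 1]
  )
  if (vec) out[1, ] else out
}

# Row-wise cross product of N x 3 matrices (or length-3 vectors).
#' @rdname quaternions
#' @export
cross3 <- function(a, b) {
  vec <- !is.matrix(a) && !is.matrix(b)
  n <- max(if (is.matrix(a)) nrow(a) else 1L, if (is.matrix(b)) nrow(b) else 1L)
  if (!is.matrix(a)) a <- matrix(a, nrow = n, ncol = 3, byrow = TRUE)
  if (!is.matrix(b)) b <- matrix(b, nrow = n, ncol = 3, byrow = TRUE)
  out <- cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
  if (vec) out[1, ] else out
}

# Rotate vectors v (N x 3 or length 3) by quaternion(s) q (length 4 or N x 4):
# v' = v + 2 w (u x v) + 2 u x (u x v), u = vector part.
#' @rdname quaternions
#' @export
quat_rotate <- function(q, v) {
  vec <- !is.matrix(v) && !is.matrix(q)
  n <- max(if (is.matrix(q)) nrow(q) else 1L, if (is.matrix(v)) nrow(v) else 1L)
  q <- as_quat_matrix(q, n)
  if (!is.matrix(v)) v <- matrix(v, nrow = n, ncol = 3, byrow = TRUE)
  u <- q[, 2:4, drop = FALSE]
  w <- q[, 1]
  uv <- cross3(u, v)
  out <- v + 2 * w * uv + 2 * cross3(u, uv)
  if (vec) out[1, ] else out
}

#' @rdname quaternions
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# Rotation-vector exponentials, vectorized over rows of rv (rad).
#' @rdname quaternions
#' @export
quat_from_rotvec <- function(rv) {
  vec <- !is.matrix(rv)
  if (!is.matrix(rv)) rv <- matrix(rv, nrow = 1)
  ang <- sqrt(rowSums(rv^2))
  half <- ang / 2
  # sin(x)/x with a series fallback near zero
  k <- ifelse(ang < 1e-12, 0.5 - ang^2 / 48, sin(half) / ang)
  out <- cbind(cos(half), rv * k)
  if (vec) out[1, ] else out
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Shortest rotation taking unit(u) onto unit(v).
#' @rdname quaternions
#' @export
quat_between <- function(u, v) {
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  d <- sum(u * v)
  if (d < -1 + 1e-12) {
    # antipodal: rotate 180 deg about any axis orthogonal to u
    ortho <- cross3(u, c(1, 0, 0))
    if (sum(ortho^2) < 1e-12) ortho <- cross3(u, c(0, 1, 0))
    return(quat_from_axis_angle(ortho, pi))
  }
  axis <- cross3(u, v)
  quat_normalize(c(1 + d, axis))
}

#' @rdname quaternions
#' @export
quat_z <- function(angle) quat_from_axis_angle(c(0, 0, 1), angle)
#' @rdname quaternions
#' @export
quat_y <- function(angle) quat_from_axis_angle(c(0, 1, 0), angle)
#' @rdname quaternions
#' @export
quat_x <- function(angle) quat_from_axis_angle(c(1, 0, 0), angle)

# z-rotation (yaw) component of a quaternion, extracted as the heading of the
# rotated x-axis projected on the ground plane.
#' @rdname quaternions
#' @export
quat_yaw <- function(q) {
  xw <- quat_rotate(q, c(1, 0, 0))
  atan2(xw[2], xw[1])
}
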