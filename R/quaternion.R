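# Quaternion algebra used throughout the package.
#
# Convention: scalar-first Hamilton quaternions c(w, x, y, z) representing the
# rotation from the sensor (body) frame to the Earth frame, so that
# v_earth = R(q) %*% v_sensor.  Euler decomposition is intrinsic z-y'-x''
# (yaw-pitch-roll), reported in the order the spine literature uses:
# lateral flexion (x), flexion-extension (y), axial rotation (z).

#' Multiply two quaternions (Hamilton product)
#'
#' @param p,q Numeric length-4 quaternions, scalar first.
#' @return The product `p %*% q` as a length-4 numeric vector.
#' @export
quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

#' Quaternion conjugate
#' @param q Length-4 quaternion or n x 4 matrix.
#' @return Conjugate with the vector part negated.
#' @export
quat_conjugate <- function(q) {
  if (is.matrix(q)) {
    q[, 2:4] <- -q[, 2:4]
    q
  } else {
    c(q[1], -q[2:4])
  }
}

#' Normalize a quaternion to unit length
#' @param q Length-4 quaternion or n x 4 matrix (row-wise).
#' @export
quat_normalize <- function(q) {
  if (is.matrix(q)) {
    q / sqrt(rowSums(q^2))
  } else {
    q / sqrt(sum(q^2))
  }
}

#' Quaternion from axis and angle
#' @param axis Length-3 rotation axis (normalized internally).
#' @param angle Rotation angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotation matrix from a unit quaternion
#' @param q Length-4 unit quaternion.
#' @return 3 x 3 rotation matrix mapping sensor-frame to Earth-frame vectors.
#' @export
rotmat_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix (Shepperd's method)
#' @param R 3 x 3 rotation matrix.
#' @export
quat_from_rotmat <- function(R) {
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

#' Rotate a vector by a quaternion
#' @param q Length-4 unit quaternion (sensor to Earth).
#' @param v Length-3 vector in the sensor frame.
#' @return `v` expressed in the Earth frame.
#' @export
quat_rotate <- function(q, v) {
  as.numeric(rotmat_from_quat(q) %*% v)
}

#' Quaternion from intrinsic z-y'-x'' Euler angles
#'
#' @param rot_z,rot_y,rot_x Rotations in radians about the z (axial rotation),
#'   then the rotated y (flexion-extension), then the doubly rotated x
#'   (lateral flexion) axis.
#' @export
quat_from_euler <- function(rot_z, rot_y, rot_x) {
  qz <- c(cos(rot_z / 2), 0, 0, sin(rot_z / 2))
  qy <- c(cos(rot_y / 2), 0, sin(rot_y / 2), 0)
  qx <- c(cos(rot_x / 2), sin(rot_x / 2), 0, 0)
  quat_multiply(quat_multiply(qz, qy), qx)
}

#' Intrinsic z-y'-x'' Euler angles from quaternions
#'
#' @param q Length-4 unit quaternion or n x 4 matrix of row quaternions.
#' @return Named vector (or n x 3 matrix) with components `x` (lateral
#'   flexion), `y` (flexion-extension) and `z` (axial rotation) in radians.
#' @export
quat_to_euler <- function(q) {
  if (!is.matrix(q)) q <- matrix(q, nrow = 1)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  sinp <- pmin(1, pmax(-1, 2 * (w * y - x * z)))
  out <- cbind(
    x = atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2)),
    y = asin(sinp),
    z = atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  )
  if (nrow(out) == 1) out[1, ] else out
}

#' Angular distance between two orientations
#' @param p,q Unit quaternions.
#' @return Smallest rotation angle (radians) taking `p` to `q`.
#' @export
quat_angle_between <- function(p, q) {
  d <- abs(sum(p * q))
  2 * acos(pmin(1, d))
}

# Row-wise Hamilton product of two n x 4 quaternion matrices.
quat_multiply_rows <- function(P, Q) {
  cbind(
    P[, 1] * Q[, 1] - P[, 2] * Q[, 2] - P[, 3] * Q[, 3] - P[, 4] * Q[, 4],
    P[, 1] * Q[, 2] + P[, 2] * Q[, 1] + P[, 3] * Q[, 4] - P[, 4] * Q[, 3],
    P[, 1] * Q[, 3] - P[, 2] * Q[, 4] + P[, 3] * Q[, 1] + P[, 4] * Q[, 2],
    P[, 1] * Q[, 4] + P[, 2] * Q[, 3] - P[, 3] * Q[, 2] + P[, 4] * Q[, 1]
  )
}

# Rotate the Earth-frame vector v into each row quaternion's sensor frame:
# returns R(q_i)^T v for all rows, as an n x 3 matrix (vectorized).
quat_rotate_inv_rows <- function(Q, v) {
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  # Columns of R are the sensor axes in Earth frame; R^T v = c(col_i . v).
  cbind(
    (1 - 2 * (y^2 + z^2)) * v[1] + 2 * (x * y + w * z) * v[2] + 2 * (x * z - w * y) * v[3],
    2 * (x * y - w * z) * v[1] + (1 - 2 * (x^2 + z^2)) * v[2] + 2 * (y * z + w * x) * v[3],
    2 * (x * z + w * y) * v[1] + 2 * (y * z - w * x) * v[2] + (1 - 2 * (x^2 + y^2)) * v[3]
  )
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
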