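# Rotation algebra: elementary rotations, intrinsic Euler composition,
# quaternions and slerp. Right-handed convention throughout; angles in
# degrees at the API surface (matching the motion-file convention),
# radians internally.

axis_index <- c(X = 1L, Y = 2L, Z = 3L)

#' Elementary rotation matrix
#'
#' @param axis one of "X", "Y", "Z".
#' @param deg rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis <- function(axis, deg) {
  a <- deg2rad(deg)
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    X = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    Y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    Z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3),
    stop_mocap("unknown axis '%s'", axis))
}

#' Compose an intrinsic Euler rotation
#'
#' Rotations are applied intrinsically in the declared order: for order
#' "ZXY" the matrix is Rz %*% Rx %*% Ry.
#'
#' @param order character vector of axes (e.g. c("Z","X","Y")) or a single
#'   string "ZXY"; may name fewer than three axes for reduced-DOF joints.
#' @param deg angles in degrees, one per axis in `order`.
#' @return 3x3 rotation matrix.
#' @export
euler_to_rotmat <- function(order, deg) {
  ax <- parse_axis_order(order)
  if (length(deg) != length(ax))
    stop_mocap("euler_to_rotmat: %d axes but %d angles", length(ax), length(deg))
  R <- diag(3)
  for (i in seq_along(ax)) R <- R %*% rot_axis(ax[i], deg[i])
  R
}

parse_axis_order <- function(order) {
  if (length(order) == 1L && nchar(order) > 1L)
    order <- strsplit(order, "")[[1]]
  order <- toupper(order)
  if (!all(order %in% c("X", "Y", "Z")))
    stop_mocap("invalid axis order: %s", paste(order, collapse = ""))
  if (anyDuplicated(order))
    stop_mocap("axis order has repeated axes: %s", paste(order, collapse = ""))
  order
}

#' Extract intrinsic Tait-Bryan angles from a rotation matrix
#'
#' Inverse of [euler_to_rotmat()] for three-axis orders. Near gimbal lock
#' (|cos(middle angle)| ~ 0) the third angle is set to zero and the first
#' absorbs the remaining rotation.
#'
#' @param R 3x3 rotation matrix.
#' @param order axis order, e.g. "ZXY".
#' @return angles in degrees, one per axis.
#' @export
rotmat_to_euler <- function(R, order) {
  ax <- parse_axis_order(order)
  if (length(ax) != 3L)
    stop_mocap("rotmat_to_euler needs a 3-axis order")
  i <- axis_index[[ax[1]]]; j <- axis_index[[ax[2]]]; k <- axis_index[[ax[3]]]
  s <- if (paste(ax, collapse = "") %in% c("XYZ", "YZX", "ZXY")) 1 else -1
  sb <- max(-1, min(1, s * R[i, k]))
  b <- asin(sb)
  if (abs(cos(b)) > 1e-9) {
    a <- atan2(-s * R[j, k], R[k, k])
    c_ <- atan2(-s * R[i, j], R[i, i])
  } else {
    c_ <- 0
    a <- atan2(s * R[j, i], R[j, j])
  }
  rad2deg(c(a, b, c_))
}

#' Quaternion from rotation matrix (w, x, y, z), unit norm, w >= 0
#' @keywords internal
quat_from_rotmat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    S <- sqrt(tr + 1) * 2
    q <- c(0.25 * S,
           (R[3, 2] - R[2, 3]) / S,
           (R[1, 3] - R[3, 1]) / S,
           (R[2, 1] - R[1, 2]) / S)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    S <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / S, 0.25 * S,
           (R[1, 2] + R[2, 1]) / S, (R[1, 3] + R[3, 1]) / S)
  } else if (R[2, 2] >= R[3, 3]) {
    S <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / S, (R[1, 2] + R[2, 1]) / S,
           0.25 * S, (R[2, 3] + R[3, 2]) / S)
  } else {
    S <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / S, (R[1, 3] + R[3, 1]) / S,
           (R[2, 3] + R[3, 2]) / S, 0.25 * S)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' @keywords internal
rotmat_from_quat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Spherical linear interpolation between unit quaternions
#'
#' Takes the shortest great-circle arc (sign-flips q2 if needed); falls
#' back to normalized linear interpolation when the quaternions are
#' nearly parallel.
#'
#' @param q1,q2 unit quaternions (w, x, y, z).
#' @param t blend weight in [0, 1].
#' @return unit quaternion.
#' @export
quat_slerp <- function(q1, q2, t) {
  d <- sum(q1 * q2)
  if (d < 0) { q2 <- -q2; d <- -d }
  if (d > 1 - 1e-10) {
    q <- (1 - t) * q1 + t * q2
  } else {
    th <- acos(max(-1, min(1, d)))
    q <- (sin((1 - t) * th) * q1 + sin(t * th) * q2) / sin(th)
  }
  q / sqrt(sum(q^2))
}
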