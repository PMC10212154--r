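# Forward kinematics and per-frame pose features: world joint positions,
# instantaneous angular velocities, root-relative coordinates, the
# five-part body partition and the 96-dimensional three-channel point
# cloud (32 joints x {x,y,z}).

#' Forward kinematics for one frame
#'
#' World position of each joint from the hierarchy, offsets and intrinsic
#' Euler rotations: position(root) = root translation; position(j) =
#' position(parent) + R(parent chain) %*% offset(j); the joint's own
#' rotation is composed onto the chain after placing the joint.
#'
#' @param sk a `skeleton`.
#' @param frame channel vector of length [n_channels()] (degrees).
#' @return J x 3 matrix of world positions (rows named by joint).
#' @export
forward_kinematics <- function(sk, frame) {
  if (length(frame) != n_channels(sk))
    stop_mocap("frame has %d channels, skeleton needs %d",
               length(frame), n_channels(sk))
  check_finite(frame, "frame channels")
  J <- length(sk$name)
  pos <- matrix(0, J, 3, dimnames = list(sk$name, c("x", "y", "z")))
  Rg <- vector("list", J)
  joint_rot <- function(j) {
    free <- sk$dof[[j]]
    if (!length(free)) return(diag(3))
    ord <- parse_axis_order(sk$rotation_order[j])
    ang <- setNames(numeric(3), ord)
    ang[free] <- frame[joint_channel_cols(sk, j)]
    euler_to_rotmat(ord, ang)
  }
  pos[1, ] <- frame[1:3]
  Rg[[1]] <- joint_rot(1L)
  for (j in seq_len(J)[-1]) {
    p <- sk$parent[j]
    pos[j, ] <- pos[p, ] + as.numeric(Rg[[p]] %*% sk$offset[j, ])
    Rg[[j]] <- Rg[[p]] %*% joint_rot(j)
  }
  pos
}

#' Instantaneous angular velocity by first differences
#'
#' v[t] = (theta[t + interval] - theta[t]) / (interval / frame_rate), per
#' channel, in degrees/second. Rotation-channel differences are wrapped
#' into (-180, 180] degrees before dividing so a 359 -> 0 degree step
#' reads as +1 degree, not -359; translation channels are differenced as
#' is (units/second).
#'
#' @param motion a `motion_sequence`.
#' @param interval frame interval (positive integer, < F).
#' @return (F - interval) x C matrix of velocities.
#' @export
angular_velocity <- function(motion, interval = 1L) {
  validate_motion(motion)
  F <- nrow(motion$frames)
  interval <- as.integer(interval)
  if (interval < 1L) stop_mocap("interval must be >= 1")
  if (interval >= F) stop_mocap("interval exceeds sequence length")
  dt <- interval / motion$frame_rate
  d <- motion$frames[(interval + 1L):F, , drop = FALSE] -
    motion$frames[1:(F - interval), , drop = FALSE]
  rot_cols <- seq_len(ncol(d)) > 3L
  d[, rot_cols] <- wrap_angle_deg(d[, rot_cols])
  d / dt
}

#' Root-relative joint coordinates
#'
#' Subtracts a per-pose reference point (the root joint or the joint
#' centroid, a proxy for the body's center of gravity) so identical
#' postures at different absolute positions coincide.
#'
#' @param positions J x 3 world positions.
#' @param reference "root" (first row) or "centroid" (column means).
#' @return J x 3 matrix of relative positions.
#' @export
root_relative <- function(positions, reference = c("root", "centroid")) {
  reference <- match.arg(reference)
  positions <- as.matrix(positions)
  check_finite(positions, "positions")
  ref <- if (reference == "root") positions[1, ] else colMeans(positions)
  sweep(positions, 2, ref)
}

#' Flatten root-relative positions into the 96-dim point cloud
#'
#' Selects the first 32 joints in skeleton order (zero-padding if there
#' are fewer) and lays the coordinates out as three channels of length
#' 32: all x, then all y, then all z.
#'
#' @param positions J x 3 root-relative positions.
#' @return numeric vector of length 96.
#' @export
build_point_cloud <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L) stop_mocap("need at least one joint")
  P <- matrix(0, 32, 3)
  n <- min(32L, nrow(positions))
  P[seq_len(n), ] <- positions[seq_len(n), ]
  as.numeric(P)   # column-major: x1..x32, y1..y32, z1..z32
}

#' Recover the 32 x 3 joint table from a 96-vector
#' @param pc numeric vector of length 96.
#' @return 32 x 3 matrix.
#' @export
unflatten_point_cloud <- function(pc) {
  if (length(pc) != 96L) stop_mocap("point cloud must have length 96")
  matrix(pc, 32, 3)
}

#' Default body-partition naming rules (CMU/BVH joint names)
#'
#' Substring rules mapping joint names to the five body parts: trunk,
#' left/right upper limb, left/right lower limb. Unmatched names fall
#' back to trunk.
#'
#' @return named list of character vectors of lowercase substrings.
#' @export
default_partition_rules <- function() {
  upper <- c("clavicle", "collar", "shoulder", "humerus", "radius", "ulna",
             "elbow", "wrist", "hand", "finger", "thumb", "arm")
  lower <- c("hip", "femur", "thigh", "knee", "tibia", "shin", "ankle",
             "foot", "toe", "heel", "leg", "upleg")
  list(
    left_upper  = paste0("l", upper),
    left_lower  = paste0("l", lower),
    right_upper = paste0("r", upper),
    right_lower = paste0("r", lower),
    trunk       = character(0)   # fallback
  )
}

#' Partition a skeleton into five body parts
#'
#' Assigns each joint to one of trunk, left_upper, left_lower,
#' right_upper, right_lower by case-insensitive substring rules on the
#' joint name; joints matching no rule go to the trunk, so the partition
#' always covers every joint exactly once.
#'
#' @param sk a `skeleton`.
#' @param name_rules named list of substring vectors (see
#'   [default_partition_rules()]).
#' @return object of class `body_partition`: named factor of parts,
#'   one element per joint.
#' @export
partition_body <- function(sk, name_rules = default_partition_rules()) {
  parts <- names(name_rules)
  lower_names <- tolower(sk$name)
  assign <- character(length(sk$name))
  for (i in seq_along(lower_names)) {
    hit <- "trunk"
    for (p in parts) {
      pats <- name_rules[[p]]
      if (length(pats) && any(vapply(pats, grepl, logical(1),
                                     x = lower_names[i], fixed = TRUE))) {
        hit <- p
        break
      }
    }
    assign[i] <- hit
  }
  structure(factor(assign, levels = unique(c(parts, "trunk"))),
            names = sk$name, class = c("body_partition", "factor"))
}

#' Per-frame pose features for a whole sequence
#'
#' Runs forward kinematics on every frame, converts to root-relative
#' coordinates and the 96-dim point cloud, and computes angular
#' velocities at the given interval (velocity rows are aligned to the
#' first frame of each difference; the trailing `interval` frames repeat
#' the last velocity so the table stays F x C).
#'
#' @param motion a `motion_sequence`.
#' @param interval frame interval for angular velocity.
#' @param reference "root" or "centroid".
#' @return list with `point_cloud` (F x 96), `velocity` (F x C),
#'   `positions` (list of J x 3), class `pose_features`.
#' @export
pose_features <- function(motion, interval = 1L, reference = "root") {
  validate_motion(motion)
  F <- nrow(motion$frames)
  pcs <- matrix(0, F, 96)
  poss <- vector("list", F)
  for (f in seq_len(F)) {
    pos <- forward_kinematics(motion$skeleton, motion$frames[f, ])
    poss[[f]] <- pos
    pcs[f, ] <- build_point_cloud(root_relative(pos, reference))
  }
  vel <- angular_velocity(motion, interval)
  vel <- rbind(vel, vel[rep(nrow(vel), interval), , drop = FALSE])
  structure(list(point_cloud = pcs, velocity = vel, positions = poss,
                 interval = interval, reference = reference),
            class = "pose_features")
}
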