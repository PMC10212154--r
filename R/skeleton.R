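# Core data model: a hierarchical skeleton (joint tree with offsets,
# per-joint Euler rotation order and free DOFs) and a motion sequence
# (per-frame root translation + joint Euler angles, degrees).

#' Construct a skeleton
#'
#' A skeleton is an ordered joint tree. Joints must be listed in
#' topological order (each parent before its children); exactly one joint
#' (the first) is the root. Angles everywhere in the package are degrees;
#' offsets are in the file's length unit.
#'
#' @param name character vector of joint names (unique).
#' @param parent integer vector of parent indices; `NA` for the root.
#' @param offset J x 3 numeric matrix of joint offsets from the parent.
#' @param rotation_order character vector, per-joint intrinsic Euler order
#'   (e.g. "ZXY").
#' @param dof list of character vectors: the free rotation axes of each
#'   joint, in channel order (subset of the joint's rotation order).
#' @return an object of class `skeleton`.
#' @export
skeleton <- function(name, parent, offset, rotation_order, dof) {
  offset <- as.matrix(offset)
  sk <- structure(
    list(name = as.character(name), parent = as.integer(parent),
         offset = offset, rotation_order = as.character(rotation_order),
         dof = dof),
    class = "skeleton")
  validate_skeleton(sk)
  sk
}

#' Validate skeleton invariants
#'
#' Checks: exactly one root; every parent index precedes its child
#' (topological order); rotation orders are permutations of distinct
#' axes; DOF axes are subsets of the rotation order.
#'
#' @param sk a `skeleton`.
#' @return the skeleton, invisibly; errors name the offending joint.
#' @export
validate_skeleton <- function(sk) {
  J <- length(sk$name)
  if (J < 1L) stop_mocap("skeleton has no joints")
  if (anyDuplicated(sk$name))
    stop_mocap("duplicate joint name: %s", sk$name[duplicated(sk$name)][1])
  roots <- which(is.na(sk$parent))
  if (length(roots) != 1L)
    stop_mocap("skeleton must have exactly one root joint, found %d", length(roots))
  if (roots != 1L)
    stop_mocap("root joint must be listed first (joint '%s')", sk$name[roots[1]])
  for (j in seq_len(J)[-1]) {
    p <- sk$parent[j]
    if (is.na(p) || p < 1L || p >= j)
      stop_mocap("joint '%s': parent index %s is not an earlier joint",
                 sk$name[j], ifelse(is.na(p), "NA", p))
  }
  if (!is.matrix(sk$offset) || nrow(sk$offset) != J || ncol(sk$offset) != 3L)
    stop_mocap("offset must be a %d x 3 matrix", J)
  for (j in seq_len(J)) {
    parse_axis_order(sk$rotation_order[j])
    free <- sk$dof[[j]]
    ord <- parse_axis_order(sk$rotation_order[j])
    if (!all(free %in% ord))
      stop_mocap("joint '%s': dof axes %s outside rotation order %s",
                 sk$name[j], paste(free, collapse = ""), sk$rotation_order[j])
  }
  invisible(sk)
}

#' Number of motion channels of a skeleton
#'
#' 3 root-translation channels plus one channel per free rotation axis.
#'
#' @param sk a `skeleton`.
#' @return integer channel count.
#' @export
n_channels <- function(sk) 3L + sum(lengths(sk$dof))

#' Channel names of a skeleton ("root.TX", "<joint>.RX", ...)
#' @param sk a `skeleton`.
#' @return character vector of length [n_channels()].
#' @export
channel_names <- function(sk) {
  nm <- c(paste0(sk$name[1], c(".TX", ".TY", ".TZ")))
  for (j in seq_along(sk$name))
    if (length(sk$dof[[j]]))
      nm <- c(nm, paste0(sk$name[j], ".R", sk$dof[[j]]))
  nm
}

# columns of the frame matrix holding joint j's rotation channels
joint_channel_cols <- function(sk, j) {
  if (!length(sk$dof[[j]])) return(integer(0))
  before <- if (j > 1L) sum(lengths(sk$dof[seq_len(j - 1L)])) else 0L
  3L + before + seq_along(sk$dof[[j]])
}

#' Construct a motion sequence
#'
#' @param sk a `skeleton`.
#' @param frames F x C numeric matrix; columns are 3 root-translation
#'   channels then per-joint Euler angles in degrees, in skeleton order.
#' @param frame_rate frames per second, > 0.
#' @return an object of class `motion_sequence`.
#' @export
motion_sequence <- function(sk, frames, frame_rate) {
  frames <- as.matrix(frames)
  ms <- structure(list(skeleton = sk, frames = frames,
                       frame_rate = as.numeric(frame_rate)),
                  class = "motion_sequence")
  validate_motion(ms)
  ms
}

#' Validate motion-sequence invariants (F >= 1, channel count, frame rate)
#' @param ms a `motion_sequence`.
#' @return the sequence, invisibly.
#' @export
validate_motion <- function(ms) {
  sk <- ms$skeleton
  if (nrow(ms$frames) < 1L) stop_mocap("motion must have at least one frame")
  if (ncol(ms$frames) != n_channels(sk))
    stop_mocap("channel mismatch: frames have %d columns, skeleton needs %d",
               ncol(ms$frames), n_channels(sk))
  if (!is.finite(ms$frame_rate) || ms$frame_rate <= 0)
    stop_mocap("frame_rate must be positive")
  invisible(ms)
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d joints, %d channels, root '%s'\n",
              length(x$name), n_channels(x), x$name[1]))
  invisible(x)
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat(sprintf("<motion_sequence> %d frames x %d channels @ %g fps (%s)\n",
              nrow(x$frames), ncol(x$frames), x$frame_rate,
              x$skeleton$name[1]))
  invisible(x)
}

same_skeleton <- function(a, b) {
  identical(a$name, b$name) && identical(a$parent, b$parent) &&
    identical(a$rotation_order, b$rotation_order) && identical(a$dof, b$dof) &&
    isTRUE(all.equal(a$offset, b$offset, tolerance = 1e-9))
}
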