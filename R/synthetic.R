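# Synthetic ground-truth generators: humanoid skeletons, styled cyclic
# motions (sinusoidal joint angles; walking / running / jumping differ
# in base frequency and amplitude), multi-camera DLT rigs with optional
# known distortion, projected marker observations with pixel noise, and
# paired two-system joint-angle waveforms with a closed-form expected
# CMC. Every generator is a pure function of (parameters, seed).

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

# 32-joint humanoid template in topological order: trunk chain + four
# limb chains; lower-limb names follow the CMU / Helen Hayes gait
# convention so the body-partition rules have realistic input. Offsets
# are meters-ish, Y up (BVH convention).
humanoid_template <- function() {
  j <- function(name, parent, off) list(name = name, parent = parent, off = off)
  list(
    j("root",      NA,          c(0, 0, 0)),
    j("sacrum",    "root",      c(0, 0.02, -0.08)),
    j("lowerback", "root",      c(0, 0.10, 0)),
    j("upperback", "lowerback", c(0, 0.12, 0)),
    j("thorax",    "upperback", c(0, 0.12, 0)),
    j("lowerneck", "thorax",    c(0, 0.10, 0)),
    j("upperneck", "lowerneck", c(0, 0.06, 0)),
    j("head",      "upperneck", c(0, 0.10, 0)),
    j("lclavicle", "thorax",    c(0.08, 0.05, 0)),
    j("lhumerus",  "lclavicle", c(0.14, 0, 0)),
    j("lradius",   "lhumerus",  c(0.26, 0, 0)),
    j("lwrist",    "lradius",   c(0.24, 0, 0)),
    j("lhand",     "lwrist",    c(0.06, 0, 0)),
    j("lfingers",  "lhand",     c(0.07, 0, 0)),
    j("lthumb",    "lhand",     c(0.03, 0, 0.03)),
    j("rclavicle", "thorax",    c(-0.08, 0.05, 0)),
    j("rhumerus",  "rclavicle", c(-0.14, 0, 0)),
    j("rradius",   "rhumerus",  c(-0.26, 0, 0)),
    j("rwrist",    "rradius",   c(-0.24, 0, 0)),
    j("rhand",     "rwrist",    c(-0.06, 0, 0)),
    j("rfingers",  "rhand",     c(-0.07, 0, 0)),
    j("rthumb",    "rhand",     c(-0.03, 0, 0.03)),
    j("lhipjoint", "root",      c(0.09, -0.05, 0)),
    j("lfemur",    "lhipjoint", c(0, -0.40, 0)),
    j("ltibia",    "lfemur",    c(0, -0.40, 0)),
    j("lfoot",     "ltibia",    c(0, -0.08, 0.12)),
    j("ltoes",     "lfoot",     c(0, 0, 0.08)),
    j("rhipjoint", "root",      c(-0.09, -0.05, 0)),
    j("rfemur",    "rhipjoint", c(0, -0.40, 0)),
    j("rtibia",    "rfemur",    c(0, -0.40, 0)),
    j("rfoot",     "rtibia",    c(0, -0.08, 0.12)),
    j("rtoes",     "rfoot",     c(0, 0, 0.08)))
}

#' Generate a humanoid-like skeleton
#'
#' Trunk chain plus four limb chains with CMU / Helen Hayes-style joint
#' names; offsets are jittered slightly by the seed. `n_joints` below
#' the 32-joint template truncates in topological order; above it,
#' extra joints are appended as a chain under the head.
#'
#' @param n_joints number of joints (>= 2; default 32, which exactly
#'   fills the 96-dim point cloud).
#' @param seed RNG seed.
#' @param jitter_sd sd of the offset jitter (0 for the exact template).
#' @return a `skeleton` (all joints 3-DOF, rotation order "ZXY").
#' @export
gen_skeleton <- function(n_joints = 32L, seed = 1L, jitter_sd = 0.005) {
  if (n_joints < 2L) stop_mocap("n_joints must be >= 2")
  tpl <- humanoid_template()
  with_seed(seed, {
    name <- vapply(tpl, `[[`, character(1), "name")
    keep <- seq_len(min(n_joints, length(tpl)))
    # drop joints whose parent was truncated away
    name <- name[keep]
    parent_name <- vapply(tpl[keep], function(x)
      if (is.null(x$parent) || is.na(x$parent[1])) NA_character_ else x$parent, character(1))
    ok <- is.na(parent_name) | parent_name %in% name
    name <- name[ok]; parent_name <- parent_name[ok]
    if (n_joints > length(tpl)) {
      extra <- n_joints - length(tpl)
      for (e in seq_len(extra)) {
        name <- c(name, sprintf("extra%d", e))
        parent_name <- c(parent_name, if (e == 1) "head" else sprintf("extra%d", e - 1))
      }
    }
    parent <- match(parent_name, name)
    offmap <- stats::setNames(lapply(tpl, `[[`, "off"),
                              vapply(tpl, `[[`, character(1), "name"))
    offset <- t(vapply(name, function(nm)
      (offmap[[nm]] %||% c(0, 0.05, 0)) +
        stats::rnorm(3, sd = jitter_sd), numeric(3)))
    offset[1, ] <- 0
    skeleton(name, parent, offset,
             rotation_order = rep("ZXY", length(name)),
             dof = rep(list(c("Z", "X", "Y")), length(name)))
  })
}

#' Style specification for cyclic motion generation
#'
#' The three built-in styles emulate walking, running and jumping as
#' cyclic skeletal motions: per-joint sinusoids whose base frequency and
#' amplitude table differ by style (walking 1 Hz / moderate amplitude,
#' running 2.5 Hz / large amplitude, jumping 0.9 Hz with a dominant
#' vertical bounce), on top of a translating, bouncing root. The
#' per-joint amplitude/phase table is drawn deterministically from the
#' style name, so the same style always moves the same way; `noise_sd`
#' is additive Gaussian angle noise in degrees.
#'
#' @param name "walking", "running" or "jumping".
#' @param noise_sd angle-noise sd in degrees (default 0.5).
#' @return list of class `style_spec`.
#' @export
style_spec <- function(name = c("walking", "running", "jumping"), noise_sd = 0.5) {
  name <- match.arg(name)
  base <- switch(name,
    walking = list(freq = 1.0, amp = 25, speed = 1.2, bounce = 0.03),
    running = list(freq = 2.5, amp = 45, speed = 3.5, bounce = 0.08),
    jumping = list(freq = 0.9, amp = 35, speed = 0.2, bounce = 0.30))
  structure(c(base, list(name = name, noise_sd = noise_sd)),
            class = "style_spec")
}

#' Generate a styled cyclic motion
#'
#' Per rotation channel: amplitude * sin(2 pi f t + phase) + N(0,
#' noise_sd^2); root translation advances at the style's speed along Z
#' with a vertical bounce at twice the base frequency. Deterministic
#' given (skeleton, style, seed).
#'
#' @param sk a `skeleton`.
#' @param style a `style_spec` (or style name).
#' @param n_frames number of frames (>= 2).
#' @param frame_rate frames per second (default 60).
#' @param seed RNG seed (noise and the per-channel amplitude jitter).
#' @return a `motion_sequence` with attribute `ground_truth`, the
#'   noise-free channel table.
#' @export
gen_motion <- function(sk, style = "walking", n_frames = 240L, frame_rate = 60,
                       seed = 1L) {
  if (is.character(style)) style <- style_spec(style)
  if (n_frames < 2L) stop_mocap("n_frames must be >= 2")
  C <- n_channels(sk)
  tt <- (seq_len(n_frames) - 1) / frame_rate
  # style-determined amplitude/phase table (independent of `seed`)
  tab <- with_seed(sum(utf8ToInt(style$name)), {
    nrot <- C - 3L
    list(amp = style$amp * stats::runif(nrot, 0.2, 1),
         phase = stats::runif(nrot, 0, 2 * pi))
  })
  clean <- matrix(0, n_frames, C)
  colnames(clean) <- channel_names(sk)
  clean[, 3] <- style$speed * tt                       # root TZ: travel
  clean[, 2] <- 0.95 + style$bounce * sin(2 * pi * 2 * style$freq * tt)  # TY: bounce
  for (ch in seq_len(C - 3L))
    clean[, 3L + ch] <- tab$amp[ch] * sin(2 * pi * style$freq * tt + tab$phase[ch])
  frames <- with_seed(seed, {
    noise <- matrix(stats::rnorm(n_frames * (C - 3L), sd = style$noise_sd),
                    n_frames, C - 3L)
    cbind(clean[, 1:3, drop = FALSE], clean[, -(1:3), drop = FALSE] + noise)
  })
  colnames(frames) <- channel_names(sk)
  ms <- motion_sequence(sk, frames, frame_rate)
  attr(ms, "ground_truth") <- clean
  ms
}

# pinhole camera -> 11 DLT parameters (denominator normalized to +1)
pinhole_to_dlt <- function(f_px, pp, R, pos) {
  K <- matrix(c(f_px, 0, 0, 0, f_px, 0, pp[1], pp[2], 1), 3, 3)
  M <- K %*% cbind(R, -R %*% pos)
  if (abs(M[3, 4]) < 1e-12) stop_mocap("camera pose degenerate for DLT normalization")
  M <- M / M[3, 4]
  c(M[1, ], M[2, ], M[3, 1:3])
}

#' Generate a circular multi-camera rig
#'
#' Cameras are spaced evenly on a circle of the given radius, at the
#' given height, all looking at the capture-volume center; the 11 DLT
#' parameters are derived from the pinhole pose/intrinsics so
#' [dlt_project()] reproduces an independent pinhole projection.
#' Optional known distortion is injected into every camera.
#'
#' @param n_cameras number of cameras (>= 2; an optical mocap stage
#'   typically uses 8).
#' @param distortion list(k1, k2, p1, p2) applied to all cameras.
#' @param seed RNG seed (angular jitter of camera placement).
#' @param radius,height circle radius and camera height (m).
#' @param target look-at point (capture-volume center).
#' @param f_px focal length in pixels; image 1280 x 1024.
#' @return list of `camera_model` objects.
#' @export
gen_camera_rig <- function(n_cameras = 8L, distortion = list(), seed = 1L,
                           radius = 3.5, height = 1.6, target = c(0, 1, 0),
                           f_px = 1200) {
  if (n_cameras < 2L) stop_mocap("need at least 2 cameras")
  dk <- utils::modifyList(list(k1 = 0, k2 = 0, p1 = 0, p2 = 0), distortion)
  sz <- c(1280, 1024); pp <- sz / 2
  with_seed(seed, {
    ang <- seq(0, 2 * pi, length.out = n_cameras + 1L)[seq_len(n_cameras)] +
      stats::runif(n_cameras, -0.05, 0.05)
    lapply(seq_len(n_cameras), function(i) {
      pos <- c(radius * cos(ang[i]), height, radius * sin(ang[i]))
      zc <- target - pos; zc <- zc / sqrt(sum(zc^2))
      up <- c(0, 1, 0)
      xc <- c(zc[2] * up[3] - zc[3] * up[2],
              zc[3] * up[1] - zc[1] * up[3],
              zc[1] * up[2] - zc[2] * up[1])
      xc <- xc / sqrt(sum(xc^2))
      yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
              zc[3] * xc[1] - zc[1] * xc[3],
              zc[1] * xc[2] - zc[2] * xc[1])
      R <- rbind(xc, yc, zc)
      camera_model(pinhole_to_dlt(f_px, pp, R, pos),
                   k1 = dk$k1, k2 = dk$k2, p1 = dk$p1, p2 = dk$p2,
                   principal_point = pp, image_size = sz)
    })
  })
}

#' Project marker trajectories into a rig, with pixel noise
#'
#' @param rig list of `camera_model` objects.
#' @param trajectories array p x f x 3 of marker world positions, or a
#'   p x 3 matrix for a single frame.
#' @param pixel_noise_sd Gaussian pixel-noise sd (default 0).
#' @param seed RNG seed.
#' @return data.frame(camera, frame, marker, u, v) with c * f * p rows;
#'   degenerate projections are excluded, with the count in attribute
#'   `n_excluded`.
#' @export
gen_observations <- function(rig, trajectories, pixel_noise_sd = 0, seed = 1L) {
  if (is.matrix(trajectories))
    trajectories <- array(trajectories, dim = c(nrow(trajectories), 1, 3))
  p <- dim(trajectories)[1]; f <- dim(trajectories)[2]
  rows <- vector("list", length(rig) * f * p)
  n_excl <- 0L; r <- 0L
  for (i in seq_along(rig)) for (j in seq_len(f)) for (k in seq_len(p)) {
    P <- trajectories[k, j, ]
    uv <- tryCatch(dlt_project(rig[[i]], P), error = function(e) NULL)
    if (is.null(uv) || !all(is.finite(uv))) { n_excl <- n_excl + 1L; next }
    r <- r + 1L
    rows[[r]] <- data.frame(camera = i, frame = j, marker = k,
                            u = uv[1, 1], v = uv[1, 2])
  }
  obs <- do.call(rbind, rows[seq_len(r)])
  if (pixel_noise_sd > 0) {
    obs <- with_seed(seed, {
      obs$u <- obs$u + stats::rnorm(nrow(obs), sd = pixel_noise_sd)
      obs$v <- obs$v + stats::rnorm(nrow(obs), sd = pixel_noise_sd)
      obs
    })
  }
  attr(obs, "n_excluded") <- n_excl
  obs
}

#' Closed-form expected CMC for the two-system generator
#'
#' For curves y_m = signal + independent N(0, sigma_m^2) noise, the
#' expected within-sample variance is the mean noise variance and the
#' total variance is approximately the signal's sample variance plus
#' that noise variance, giving E[CMC] ~ sqrt(1 - sn2 / (var(signal) +
#' sn2)) with sn2 = (sd_a^2 + sd_b^2) / 2.
#'
#' @param signal the noise-free waveform (degrees).
#' @param noise_sd_a,noise_sd_b per-system noise sd (degrees).
#' @return expected CMC value.
#' @export
expected_cmc_two_system <- function(signal, noise_sd_a, noise_sd_b) {
  vs <- mean((signal - mean(signal))^2)
  sn2 <- (noise_sd_a^2 + noise_sd_b^2) / 2
  sqrt(max(0, 1 - sn2 / (vs + sn2)))
}

#' Generate paired two-system joint-angle recordings
#'
#' System A trials are `signal + offset + N(0, noise_sd_a^2)`; system B
#' trials are `signal + N(0, noise_sd_b^2)`. The constant offset
#' emulates the calibration difference between an optical and an
#' inertial measurement chain and is removed by mean-shift alignment.
#'
#' @param signal N-vector, the underlying joint-angle waveform (degrees).
#' @param offset constant inter-system offset (degrees).
#' @param noise_sd_a,noise_sd_b per-system noise sd (degrees).
#' @param n_trials trials per system (>= 2).
#' @param seed RNG seed.
#' @param joint,plane metadata for the waveform objects.
#' @return list with `system_a`, `system_b` (each a
#'   `joint_angle_waveform`) and `expected_cmc`.
#' @export
gen_two_system_waveforms <- function(signal, offset = 0, noise_sd_a = 1,
                                     noise_sd_b = 1, n_trials = 5L, seed = 1L,
                                     joint = "hip", plane = "flexion_extension") {
  if (n_trials < 2L) stop_mocap("n_trials must be >= 2")
  N <- length(signal)
  with_seed(seed, {
    A <- t(replicate(n_trials, signal + offset + stats::rnorm(N, sd = noise_sd_a)))
    B <- t(replicate(n_trials, signal + stats::rnorm(N, sd = noise_sd_b)))
    list(system_a = joint_angle_waveform(joint, plane, "optical", A),
         system_b = joint_angle_waveform(joint, plane, "inertial", B),
         expected_cmc = expected_cmc_two_system(signal, noise_sd_a, noise_sd_b))
  })
}
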