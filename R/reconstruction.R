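# Direct linear transformation (DLT) camera model, calibration,
# multi-camera triangulation by uncertainty minimization, lens-distortion
# refinement, and reconstruction-uncertainty statistics.
#
# Projection convention (11-parameter DLT, "+1" denominator):
#   u = (L1 x + L2 y + L3 z + L4) / (L9 x + L10 y + L11 z + 1) + du
#   v = (L5 x + L6 y + L7 z + L8) / (L9 x + L10 y + L11 z + 1) + dv
# du, dv are the nonlinear optical errors, modeled as radial (k1, k2) +
# tangential (p1, p2) polynomial distortion about the principal point in
# pixel-normalized coordinates (normalization scale = width / 2).
# Residuals dU, dV of an observed point against a reconstruction define
# the uncertainty eps = (1/c) * sum_i (dU_i^2 + dV_i^2) of one
# (frame, marker); averaging over frames gives the single-marker
# uncertainty eps_a and over markers the multi-marker eps_b.

#' Construct a DLT camera model
#'
#' @param L numeric vector of the 11 DLT parameters L1..L11.
#' @param k1,k2 radial distortion coefficients (pixel-normalized).
#' @param p1,p2 tangential distortion coefficients.
#' @param principal_point (u0, v0) in pixels.
#' @param image_size (width, height) in pixels.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(L, k1 = 0, k2 = 0, p1 = 0, p2 = 0,
                         principal_point = image_size / 2,
                         image_size = c(1280, 1024)) {
  L <- as.numeric(L)
  if (length(L) != 11L) stop_mocap("camera needs exactly 11 DLT parameters")
  check_finite(c(L, k1, k2, p1, p2), "camera parameters")
  structure(list(L = L, k1 = k1, k2 = k2, p1 = p1, p2 = p2,
                 principal_point = as.numeric(principal_point),
                 image_size = as.numeric(image_size)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %dx%d px, k1=%.4g k2=%.4g p1=%.4g p2=%.4g\n",
              x$image_size[1], x$image_size[2], x$k1, x$k2, x$p1, x$p2))
  invisible(x)
}

distortion_scale <- function(camera) camera$image_size[1] / 2

# distortion displacement (du, dv) at ideal pixel position(s); uv is n x 2
distortion_delta <- function(camera, uv) {
  uv <- matrix(uv, ncol = 2)
  s <- distortion_scale(camera)
  x <- (uv[, 1] - camera$principal_point[1]) / s
  y <- (uv[, 2] - camera$principal_point[2]) / s
  r2 <- x^2 + y^2
  radial <- camera$k1 * r2 + camera$k2 * r2^2
  dx <- x * radial + 2 * camera$p1 * x * y + camera$p2 * (r2 + 2 * x^2)
  dy <- y * radial + camera$p1 * (r2 + 2 * y^2) + 2 * camera$p2 * x * y
  cbind(du = s * dx, dv = s * dy)
}

# ideal (undistorted) DLT projection; points is n x 3
dlt_project_ideal <- function(camera, points) {
  points <- matrix(points, ncol = 3)
  L <- camera$L
  den <- L[9] * points[, 1] + L[10] * points[, 2] + L[11] * points[, 3] + 1
  if (any(abs(den) < 1e-12))
    stop_mocap("degenerate point: projection denominator ~ 0")
  cbind(u = (L[1] * points[, 1] + L[2] * points[, 2] + L[3] * points[, 3] + L[4]) / den,
        v = (L[5] * points[, 1] + L[6] * points[, 2] + L[7] * points[, 3] + L[8]) / den)
}

#' Project a 3D point through a DLT camera
#'
#' Applies the 11-parameter projective mapping and then the nonlinear
#' distortion displacement evaluated at the undistorted projection.
#'
#' @param camera a `camera_model`.
#' @param points 3-vector or n x 3 matrix of object-space points.
#' @return n x 2 matrix of pixel coordinates (u, v).
#' @export
dlt_project <- function(camera, points) {
  ideal <- dlt_project_ideal(camera, points)
  ideal + distortion_delta(camera, ideal)
}

# invert the distortion map by fixed-point iteration: find ideal uv such
# that ideal + delta(ideal) = observed
undistort_uv <- function(camera, uv, iters = 25L) {
  uv <- matrix(uv, ncol = 2)
  if (camera$k1 == 0 && camera$k2 == 0 && camera$p1 == 0 && camera$p2 == 0)
    return(uv)
  ideal <- uv
  for (i in seq_len(iters)) ideal <- uv - distortion_delta(camera, ideal)
  ideal
}

#' Calibrate the 11 DLT parameters from control points
#'
#' Linear least squares on the rearranged projection equations:
#' each control point contributes two rows
#' `x y z 1 0 0 0 0 -ux -uy -uz | u` and the v analogue. Needs at least
#' 6 non-coplanar points; distortion is returned zeroed.
#'
#' @param points3d n x 3 object-space coordinates.
#' @param uv n x 2 observed pixel coordinates.
#' @param image_size,principal_point camera metadata carried onto the
#'   returned model.
#' @return a `camera_model` with fitted L and zero distortion.
#' @export
dlt_calibrate <- function(points3d, uv,
                          image_size = c(1280, 1024),
                          principal_point = image_size / 2) {
  points3d <- matrix(points3d, ncol = 3)
  uv <- matrix(uv, ncol = 2)
  n <- nrow(points3d)
  if (n != nrow(uv)) stop_mocap("points3d and uv row counts differ")
  if (n < 6L) stop_mocap("rank-deficient: need >= 6 control points, got %d", n)
  A <- matrix(0, 2 * n, 11)
  b <- numeric(2 * n)
  x <- points3d[, 1]; y <- points3d[, 2]; z <- points3d[, 3]
  A[seq(1, 2 * n, 2), ] <- cbind(x, y, z, 1, 0, 0, 0, 0,
                                 -uv[, 1] * x, -uv[, 1] * y, -uv[, 1] * z)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, 0, x, y, z, 1,
                                 -uv[, 2] * x, -uv[, 2] * y, -uv[, 2] * z)
  b[seq(1, 2 * n, 2)] <- uv[, 1]
  b[seq(2, 2 * n, 2)] <- uv[, 2]
  qrA <- qr(A)
  if (qrA$rank < 11L)
    stop_mocap("rank-deficient control-point configuration (rank %d < 11); are the points coplanar?",
               qrA$rank)
  L <- qr.coef(qrA, b)
  camera_model(L, principal_point = principal_point, image_size = image_size)
}

#' Triangulate one marker from multi-camera observations
#'
#' Solves the linear rearrangement of the projection equations across
#' cameras (after undistorting the observations), then optionally
#' polishes the point by directly minimizing the uncertainty
#' eps = (1/c) sum_i (dU_i^2 + dV_i^2) with a quasi-Newton step.
#'
#' @param cameras list of `camera_model` (length >= 2).
#' @param uv c x 2 matrix of observed pixels, one row per camera.
#' @param polish run the nonlinear refinement (default TRUE).
#' @return list with `point` (3-vector), `epsilon` (achieved Eq-5
#'   uncertainty, px^2), `condition` (linear design condition number) and
#'   `ill_conditioned` flag (condition > 1e10).
#' @export
triangulate <- function(cameras, uv, polish = TRUE) {
  uv <- matrix(uv, ncol = 2)
  c_ <- length(cameras)
  if (c_ < 2L) stop_mocap("under-determined: triangulation needs >= 2 cameras")
  if (nrow(uv) != c_) stop_mocap("one observation row per camera required")
  A <- matrix(0, 2 * c_, 3); b <- numeric(2 * c_)
  for (i in seq_len(c_)) {
    L <- cameras[[i]]$L
    id <- undistort_uv(cameras[[i]], uv[i, , drop = FALSE])
    u <- id[1, 1]; v <- id[1, 2]
    A[2 * i - 1, ] <- c(u * L[9] - L[1], u * L[10] - L[2], u * L[11] - L[3])
    A[2 * i, ]     <- c(v * L[9] - L[5], v * L[10] - L[6], v * L[11] - L[7])
    b[2 * i - 1] <- L[4] - u
    b[2 * i]     <- L[8] - v
  }
  sv <- svd(A)$d
  cond <- sv[1] / max(sv[3], .Machine$double.eps)
  X <- qr.coef(qr(A), b)
  eps_of <- function(P) {
    r <- uv - t(vapply(cameras, function(cm) dlt_project(cm, P)[1, ], numeric(2)))
    sum(r^2) / c_
  }
  if (polish) {
    opt <- stats::optim(X, eps_of, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 200))
    if (is.finite(opt$value) && opt$value <= eps_of(X)) X <- opt$par
  }
  list(point = as.numeric(X), epsilon = eps_of(X), condition = cond,
       ill_conditioned = cond > 1e10)
}

#' Reconstruction-uncertainty statistics over an observation table
#'
#' For every observation (camera i, frame j, marker k) the residuals
#' dU, dV against the reprojected reconstruction are squared and
#' averaged: per (frame, marker) point uncertainty eps (over c cameras),
#' per-marker uncertainty eps_a (over c cameras x f frames) and overall
#' eps_b (over c x f x p). eps_b equals the marker-mean of eps_a by
#' construction.
#'
#' @param cameras list of `camera_model`; observation `camera` indices
#'   refer into this list.
#' @param observations data.frame with columns camera, frame, marker, u, v.
#' @param reconstructions data.frame with columns frame, marker, x, y, z.
#' @return object of class `uncertainty_report`: list with
#'   `epsilon_point` (data.frame frame, marker, epsilon), `epsilon_single`
#'   (named per-marker eps_a), `epsilon_multi` (eps_b), and c, f, p.
#' @export
uncertainty_stats <- function(cameras, observations, reconstructions) {
  need <- c("camera", "frame", "marker", "u", "v")
  if (!all(need %in% names(observations)))
    stop_mocap("observations need columns %s", paste(need, collapse = ", "))
  obs <- observations
  key <- paste(obs$frame, obs$marker)
  nobs <- table(key)
  if (any(nobs < 2L)) {
    bad <- names(nobs)[nobs < 2L]
    stop_mocap("missing observations: (frame, marker) pairs with < 2 cameras: %s",
               paste(bad, collapse = "; "))
  }
  rec_key <- paste(reconstructions$frame, reconstructions$marker)
  miss <- setdiff(unique(key), rec_key)
  if (length(miss))
    stop_mocap("no reconstruction for (frame, marker): %s", paste(miss, collapse = "; "))
  ri <- match(key, rec_key)
  P <- as.matrix(reconstructions[, c("x", "y", "z")])
  res2 <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    pr <- dlt_project(cameras[[obs$camera[i]]], P[ri[i], , drop = FALSE])
    res2[i] <- (obs$u[i] - pr[1, 1])^2 + (obs$v[i] - pr[1, 2])^2
  }
  c_ <- length(cameras)
  f_ <- length(unique(obs$frame))
  p_ <- length(unique(obs$marker))
  eps_point <- stats::aggregate(res2, by = list(frame = obs$frame, marker = obs$marker),
                                FUN = function(r) sum(r) / c_)
  names(eps_point)[3] <- "epsilon"
  per_marker <- tapply(res2, obs$marker, sum) / (c_ * f_)
  eps_b <- sum(res2) / (c_ * f_ * p_)
  structure(list(epsilon_point = eps_point,
                 epsilon_single = per_marker,
                 epsilon_multi = eps_b,
                 c = c_, f = f_, p = p_),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("<uncertainty_report> c=%d f=%d p=%d  eps_b=%.6g px^2\n",
              x$c, x$f, x$p, x$epsilon_multi))
  invisible(x)
}

#' Two-step iterative distortion refinement
#'
#' Alternates: (1) re-fit the 11 DLT parameters on control points whose
#' observations fall in the low-distortion central region of the image
#' (default the central 50% x 50% box), after removing the current
#' distortion estimate from the observations; (2) fit (k1, k2, p1, p2)
#' by linear least squares on all points holding L fixed. Stops when the
#' all-point reprojection RMS improves by less than `tol` or after
#' `max_iters`; the reported RMS trace is non-increasing (a step that
#' would worsen RMS is rolled back and iteration stops).
#'
#' @param camera initial `camera_model` (L calibrated, e.g. by
#'   [dlt_calibrate()]).
#' @param points3d n x 3 control-point coordinates.
#' @param uv n x 2 observed pixels.
#' @param max_iters,tol stopping controls.
#' @param central_frac linear fraction of the image treated as the
#'   low-distortion center (0.5 = central 50% box).
#' @return refined `camera_model` with attribute `rms_trace` (pixel RMS
#'   per iteration, starting with the input model's RMS).
#' @export
refine_distortion <- function(camera, points3d, uv, max_iters = 20L,
                              tol = 1e-10, central_frac = 0.5) {
  points3d <- matrix(points3d, ncol = 3)
  uv <- matrix(uv, ncol = 2)
  pp <- camera$principal_point; sz <- camera$image_size
  central <- abs(uv[, 1] - pp[1]) <= central_frac * sz[1] / 2 &
             abs(uv[, 2] - pp[2]) <= central_frac * sz[2] / 2
  if (!any(central))
    stop_mocap("configuration error: no control points in the central image region")
  if (sum(central) < 6L)
    stop_mocap("configuration error: only %d central control points (< 6)", sum(central))
  rms_of <- function(cm) {
    r <- uv - dlt_project(cm, points3d)
    sqrt(mean(r^2))
  }
  best <- camera
  trace <- rms_of(best)
  for (it in seq_len(max_iters)) {
    cur <- best
    # step 1: refit L on central points, observations corrected for
    # the current distortion estimate
    uv_corr <- undistort_uv(cur, uv)
    cm_lin <- dlt_calibrate(points3d[central, , drop = FALSE],
                            uv_corr[central, , drop = FALSE],
                            image_size = sz, principal_point = pp)
    cur$L <- cm_lin$L
    # step 2: distortion is linear in (k1,k2,p1,p2) given the ideal
    # projections; solve the 2n x 4 least-squares problem
    ideal <- dlt_project_ideal(cur, points3d)
    s <- distortion_scale(cur)
    x <- (ideal[, 1] - pp[1]) / s
    y <- (ideal[, 2] - pp[2]) / s
    r2 <- x^2 + y^2
    D <- rbind(cbind(x * r2, x * r2^2, 2 * x * y, r2 + 2 * x^2),
               cbind(y * r2, y * r2^2, r2 + 2 * y^2, 2 * x * y)) * s
    rhs <- c(uv[, 1] - ideal[, 1], uv[, 2] - ideal[, 2])
    k <- qr.coef(qr(D), rhs)
    k[is.na(k)] <- 0
    cur$k1 <- k[1]; cur$k2 <- k[2]; cur$p1 <- k[3]; cur$p2 <- k[4]
    new_rms <- rms_of(cur)
    if (new_rms > utils::tail(trace, 1)) break   # roll back, keep best
    improved <- utils::tail(trace, 1) - new_rms
    best <- cur
    trace <- c(trace, new_rms)
    if (improved < tol) break
  }
  attr(best, "rms_trace") <- trace
  best
}
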