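# DLT projection, calibration, triangulation, uncertainty statistics and
# two-step distortion refinement

test_that("dlt_project: identity-like mapping, origin case, formula oracle", {
  cam <- camera_model(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(dlt_project(cam, c(2, 3, 5))[1, ]), c(2, 3))

  set.seed(1)
  L <- rnorm(11, sd = 0.3)
  cam2 <- camera_model(L)
  expect_equal(unname(dlt_project(cam2, c(0, 0, 0))[1, ]), c(L[4], L[8]))

  for (i in 1:20) {
    set.seed(i)
    L <- c(rnorm(8, sd = 100), rnorm(3, sd = 0.05))
    cam3 <- camera_model(L, k1 = -0.2, k2 = 0.05, p1 = 0.01, p2 = -0.02,
                         principal_point = c(640, 512), image_size = c(1280, 1024))
    P <- rnorm(3)
    expect_equal(unname(dlt_project(cam3, P)[1, ]),
                 oracle_dlt_uv(L, -0.2, 0.05, 0.01, -0.02, c(640, 512), 640, P),
                 tolerance = 1e-12)
  }
  expect_error(dlt_project(camera_model(c(rep(0, 8), 0, 0, -1)), c(0, 0, 1)),
               "degenerate")
})

test_that("dlt_calibrate recovers an exact camera and rejects bad input", {
  rig <- gen_camera_rig(2, seed = 3)
  set.seed(4)
  pts <- cbind(runif(8, -0.5, 0.5), runif(8, 0.5, 1.5), runif(8, -0.5, 0.5))
  uv <- dlt_project(rig[[1]], pts)
  cal <- dlt_calibrate(pts, uv)
  expect_lt(sqrt(mean((dlt_project(cal, pts) - uv)^2)), 1e-8)

  expect_error(dlt_calibrate(pts[1:5, ], uv[1:5, ]), "6 control points")
  coplanar <- cbind(runif(10, -1, 1), runif(10, -1, 1), 1)
  uv_cop <- dlt_project(rig[[1]], coplanar)
  expect_error(dlt_calibrate(coplanar, uv_cop), "rank")
})

test_that("calibration reprojection RMS tracks the pixel-noise floor", {
  rig <- gen_camera_rig(2, seed = 5)
  sigma <- 0.5
  set.seed(100)
  rms <- replicate(10, {
    pts <- cbind(runif(50, -0.5, 0.5), runif(50, 0.5, 1.5), runif(50, -0.5, 0.5))
    uv <- dlt_project(rig[[1]], pts) + rnorm(100, sd = sigma)
    cal <- dlt_calibrate(pts, uv)
    sqrt(mean((dlt_project(cal, pts) - uv)^2))
  })
  expect_gt(median(rms), sigma / 2)
  expect_lt(median(rms), sigma * 2)
})

test_that("triangulation: exact recovery, plug-in identity, NLS oracle", {
  rig <- gen_camera_rig(2, seed = 6)
  P <- c(0.2, 1.3, -0.4)
  uv <- do.call(rbind, lapply(rig, function(cm) dlt_project(cm, P)))
  tri <- triangulate(rig, uv)
  expect_lt(max(abs(tri$point - P)), 1e-8)
  expect_lt(tri$epsilon, 1e-15)
  expect_error(triangulate(rig[1], uv[1, , drop = FALSE]), "under-determined")

  # residuals dU = dV = d for all c cameras give eps = 2 d^2 exactly
  d <- 0.37
  uv_shift <- uv + d
  r <- uv_shift - do.call(rbind, lapply(rig, function(cm) dlt_project(cm, tri$point)))
  eps_direct <- sum(r^2) / length(rig)
  expect_equal(eps_direct, 2 * d^2, tolerance = 1e-9)

  # noisy 4-camera case vs multi-start nonlinear least squares
  rig4 <- gen_camera_rig(4, seed = 7)
  set.seed(8)
  uv4 <- do.call(rbind, lapply(rig4, function(cm) dlt_project(cm, P))) +
    rnorm(8, sd = 0.3)
  tri4 <- triangulate(rig4, uv4)
  eps_of <- function(X) {
    r <- uv4 - do.call(rbind, lapply(rig4, function(cm) dlt_project(cm, X)))
    sum(r^2) / 4
  }
  best <- Inf; best_X <- NULL
  set.seed(9)
  for (s in 1:50) {
    st <- P + rnorm(3, sd = 0.5)
    o <- optim(st, eps_of, method = "BFGS", control = list(reltol = 1e-15))
    if (o$value < best) { best <- o$value; best_X <- o$par }
  }
  expect_lt(max(abs(tri4$point - best_X)), 1e-6)
  expect_equal(tri4$epsilon, best, tolerance = 1e-6)
})

test_that("residual sums vanish at the optimum of a symmetric 2-camera rig", {
  # symmetric rig: mirrored cameras, symmetric observations -> the
  # least-squares optimum balances residuals so their camera sums vanish
  rig <- gen_camera_rig(2, seed = 10, radius = 3, height = 1, target = c(0, 1, 0))
  P <- c(0.1, 1.2, 0.3)
  uv <- do.call(rbind, lapply(rig, function(cm) dlt_project(cm, P)))
  tri <- triangulate(rig, uv)
  r <- uv - do.call(rbind, lapply(rig, function(cm) dlt_project(cm, tri$point)))
  expect_lt(abs(sum(r[, 1])), 1e-8)
  expect_lt(abs(sum(r[, 2])), 1e-8)
})

test_that("uncertainty statistics: zeros, p=1 reduction, triple-loop oracle", {
  rig <- gen_camera_rig(3, seed = 11)
  set.seed(12)
  traj <- array(runif(5 * 4 * 3, -0.3, 0.3), dim = c(5, 4, 3))
  traj[, , 2] <- traj[, , 2] + 1
  obs <- gen_observations(rig, traj)
  expect_identical(nrow(obs), 3L * 4L * 5L)
  rec <- do.call(rbind, lapply(1:4, function(j) data.frame(
    frame = j, marker = 1:5, x = traj[, j, 1], y = traj[, j, 2], z = traj[, j, 3])))
  rep0 <- uncertainty_stats(rig, obs, rec)
  expect_lt(max(rep0$epsilon_single), 1e-18)
  expect_lt(rep0$epsilon_multi, 1e-18)

  # noisy observations: eps_b = mean_k eps_a(k) and the direct sums agree
  obs_n <- gen_observations(rig, traj, pixel_noise_sd = 0.7, seed = 13)
  rep1 <- uncertainty_stats(rig, obs_n, rec)
  expect_equal(rep1$epsilon_multi, mean(rep1$epsilon_single), tolerance = 1e-12)
  # independent triple loop over the residual table
  total <- 0
  for (i in seq_len(nrow(obs_n))) {
    cm <- rig[[obs_n$camera[i]]]
    pr <- dlt_project(cm, traj[obs_n$marker[i], obs_n$frame[i], ])
    total <- total + unname((obs_n$u[i] - pr[1, 1])^2 + (obs_n$v[i] - pr[1, 2])^2)
  }
  expect_equal(rep1$epsilon_multi, total / (3 * 4 * 5), tolerance = 1e-12)

  # single marker: eps_b equals eps_a exactly
  obs_p1 <- obs_n[obs_n$marker == 1, ]
  rec_p1 <- rec[rec$marker == 1, ]
  rep_p1 <- uncertainty_stats(rig, obs_p1, rec_p1)
  expect_equal(rep_p1$epsilon_multi, unname(rep_p1$epsilon_single[1]),
               tolerance = 1e-15)

  drop_idx <- which(obs_n$frame == 1 & obs_n$marker == 1)[1:2]
  expect_error(uncertainty_stats(rig, obs_n[-drop_idx, ], rec), "< 2 cameras")
})

test_that("distortion refinement recovers injected k1 and is monotone", {
  rig <- gen_camera_rig(2, seed = 14, distortion = list(k1 = -0.2))
  cam_true <- rig[[1]]
  set.seed(15)
  pts <- cbind(runif(60, -1.2, 1.2), runif(60, 0.2, 2.0), runif(60, -1.2, 1.2))
  uv <- dlt_project(cam_true, pts)
  init <- dlt_calibrate(pts, uv, image_size = cam_true$image_size,
                        principal_point = cam_true$principal_point)
  ref <- refine_distortion(init, pts, uv, max_iters = 30)
  expect_lt(abs(ref$k1 - (-0.2)), 1e-3)
  trace <- attr(ref, "rms_trace")
  expect_true(all(diff(trace) <= 1e-12))

  # zero-distortion data: distortion stays ~0, terminates in <= 2 iters
  rig0 <- gen_camera_rig(2, seed = 16)
  uv0 <- dlt_project(rig0[[1]], pts)
  init0 <- dlt_calibrate(pts, uv0, image_size = rig0[[1]]$image_size,
                         principal_point = rig0[[1]]$principal_point)
  ref0 <- refine_distortion(init0, pts, uv0)
  expect_lt(max(abs(c(ref0$k1, ref0$k2, ref0$p1, ref0$p2))), 1e-8)
  expect_lte(length(attr(ref0, "rms_trace")), 3L)   # initial + <= 2 iterations

  # no central points -> configuration error
  edge_uv <- uv
  edge_uv[, 1] <- ifelse(edge_uv[, 1] > 640, 1270, 5)
  expect_error(refine_distortion(init, pts, edge_uv), "central")
})

test_that("epsilon scales as sigma^2 under i.i.d. pixel noise", {
  rig <- gen_camera_rig(3, seed = 17)
  set.seed(18)
  sigmas <- c(0.1, 0.3, 1.0)
  mean_eps <- vapply(seq_along(sigmas), function(si) {
    eps <- replicate(60, {
      P <- c(runif(1, -0.3, 0.3), runif(1, 0.8, 1.4), runif(1, -0.3, 0.3))
      uv <- do.call(rbind, lapply(rig, function(cm) dlt_project(cm, P))) +
        rnorm(6, sd = sigmas[si])
      triangulate(rig, uv, polish = FALSE)$epsilon
    })
    mean(eps)
  }, numeric(1))
  slope <- coef(lm(log(mean_eps) ~ log(sigmas)))[2]
  expect_gt(slope, 1.8); expect_lt(slope, 2.2)
})
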