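# convolutional RBM: energy, conditionals, exact likelihood against
# brute-force enumeration, CD training and similar-frame detection

test_that("energy: zero-parameter case, filter symmetry, dense oracle", {
  m0 <- conv_rbm(n_positions = 4, n_channels = 2, n_filters = 2,
                 kernel_width = 2, init_sd = 0, seed = 1)
  v <- matrix(seq(-1, 1, length.out = 8), 2, 4)
  h <- matrix(rbinom(2 * 3, 1, 0.5), 2, 3)
  expect_equal(rbm_energy(m0, v, h), sum(v^2) / 2, tolerance = 1e-12)

  # identical filters: energy invariant under swapping their unit states
  m <- conv_rbm(n_positions = 4, n_channels = 1, n_filters = 2,
                kernel_width = 2, init_sd = 0.3, seed = 2)
  m$W[2, , ] <- m$W[1, , ]
  m$hidden_bias[2] <- m$hidden_bias[1]
  v1 <- matrix(rnorm(4), 1, 4)
  hA <- rbind(c(1, 0, 1), c(0, 1, 0))
  hB <- hA[2:1, ]
  expect_equal(rbm_energy(m, v1, hA), rbm_energy(m, v1, hB), tolerance = 1e-12)

  # dense oracle on random parameters
  mt <- tiny_rbm(seed = 3)
  set.seed(4)
  v2 <- matrix(rbinom(3, 1, 0.5), 1, 3)
  h2 <- matrix(rbinom(2, 1, 0.5), 2, 1)
  expect_equal(rbm_energy(mt, v2, h2), oracle_rbm_energy(mt, v2, h2),
               tolerance = 1e-12)
  expect_error(rbm_energy(mt, v2, matrix(0, 3, 1)), "hidden states")
})

test_that("partition function and P(h|v) match brute-force enumeration", {
  mt <- tiny_rbm(seed = 5)
  enum <- oracle_rbm_enumeration(mt)
  ll <- rbm_exact_loglik(mt, lapply(seq_len(nrow(enum$vstates)), function(i)
    matrix(enum$vstates[i, ], 1, 3)))
  expect_equal(ll$log_z, log(enum$Z), tolerance = 1e-10)
  expect_equal(ll$loglik, log(enum$marginal / enum$Z), tolerance = 1e-10)
  expect_equal(sum(exp(ll$loglik)), 1, tolerance = 1e-10)

  # conditional from the enumerated joint: P(h_k = 1 | v)
  v <- matrix(c(1, 0, 1), 1, 3)
  hstates <- as.matrix(expand.grid(0:1, 0:1))
  joint <- vapply(seq_len(4), function(ih)
    exp(-oracle_rbm_energy(mt, v, matrix(as.numeric(hstates[ih, ]), 2, 1))),
    numeric(1))
  p_brute <- c(sum(joint[hstates[, 1] == 1]), sum(joint[hstates[, 2] == 1])) / sum(joint)
  expect_equal(as.numeric(hidden_conditional(mt, v)), p_brute, tolerance = 1e-12)
})

test_that("hidden conditional: sigmoid(0) = 0.5 and bias monotonicity", {
  m0 <- conv_rbm(n_positions = 6, n_channels = 3, n_filters = 4,
                 kernel_width = 3, init_sd = 0, seed = 1)
  v <- matrix(rnorm(18), 3, 6)
  expect_true(all(hidden_conditional(m0, v) == 0.5))

  m1 <- conv_rbm(n_positions = 6, n_channels = 3, n_filters = 4,
                 kernel_width = 3, init_sd = 0.2, seed = 6)
  p_before <- hidden_conditional(m1, v)
  m1$hidden_bias[2] <- m1$hidden_bias[2] + 1.5
  p_after <- hidden_conditional(m1, v)
  expect_true(all(p_after[2, ] > p_before[2, ]))
  expect_equal(p_after[-2, ], p_before[-2, ], tolerance = 1e-15)
  expect_true(all(p_after > 0 & p_after < 1))
})

test_that("history_order = 0 path reduces exactly to the plain RBM", {
  m_ar <- conv_rbm(n_positions = 5, n_channels = 2, n_filters = 3,
                   kernel_width = 2, history_order = 2, init_sd = 0.3, seed = 7)
  m_plain <- m_ar; m_plain$A <- NULL; m_plain$B <- NULL
  m_plain$history_order <- 0L
  v <- matrix(rnorm(10), 2, 5)
  h <- matrix(rbinom(3 * 4, 1, 0.5), 3, 4)
  # zero AR weights: conditionals and energies identical with any history
  hist <- list(matrix(rnorm(10), 2, 5), matrix(rnorm(10), 2, 5))
  expect_identical(rbm_energy(m_ar, v, h, history = hist),
                   rbm_energy(m_plain, v, h))
  expect_identical(hidden_conditional(m_ar, v, history = hist),
                   hidden_conditional(m_plain, v))
  # nonzero AR weights do shift the conditionals
  m_ar$B[1, ] <- 2
  expect_false(identical(hidden_conditional(m_ar, v, history = hist),
                         hidden_conditional(m_plain, v)))
})

test_that("train_cd: lr = 0 no-op, determinism, likelihood improvement", {
  mt <- tiny_rbm(seed = 8)
  data <- sample_tiny_rbm(tiny_rbm(seed = 20, sd = 1.2), 120, seed = 9)

  noop <- train_cd(mt, data, lr = 0, epochs = 2, seed = 10)
  expect_identical(noop$W, mt$W)
  expect_identical(noop$hidden_bias, mt$hidden_bias)

  r1 <- train_cd(mt, data, lr = 0.05, epochs = 4, seed = 11)
  r2 <- train_cd(mt, data, lr = 0.05, epochs = 4, seed = 11)
  expect_identical(r1$W, r2$W)
  expect_identical(attr(r1, "recon_trace"), attr(r2, "recon_trace"))

  trained <- train_cd(mt, data, k = 1, lr = 0.1, epochs = 30, batch = 16, seed = 12)
  ll_init <- mean(rbm_exact_loglik(mt, data)$loglik)
  ll_trained <- mean(rbm_exact_loglik(trained, data)$loglik)
  expect_gt(ll_trained, ll_init)
})

test_that("encode: shape contract, duplicate frames, style separation", {
  sk <- gen_skeleton(32, seed = 13)
  walk <- pose_features(gen_motion(sk, "walking", n_frames = 240, seed = 14))
  run <- pose_features(gen_motion(sk, "running", n_frames = 240, seed = 15))
  stats <- feature_stats(rbind(walk$point_cloud, run$point_cloud))
  model <- conv_rbm(n_filters = 8, kernel_width = 9, input_mode = "dynamics",
                    seed = 16)
  slabs <- c(encode_slabs(model, walk$point_cloud, stats),
             encode_slabs(model, run$point_cloud, stats))
  model <- train_cd(model, slabs, epochs = 10, lr = 1e-3, seed = 17)

  emb <- encode(model, walk$point_cloud, stats = stats)
  expect_identical(dim(unclass(emb)), c(240L, 8L))
  expect_true(all(is.finite(emb)))

  # identical frames with identical velocity context embed identically
  dup <- walk$point_cloud[c(1, 2, 1, 2), ]
  edup <- encode(model, dup, stats = stats)
  expect_equal(edup[2, ], edup[4, ], tolerance = 1e-15)

  # styles with different frequency content separate in embedding space
  # (shared standardization; brute-force pairwise distances)
  ew <- unclass(encode(model, walk$point_cloud, stats = stats))
  er <- unclass(encode(model, run$point_cloud, stats = stats))
  dmat <- function(A, B)
    sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0))
  within <- (mean(dmat(ew, ew)) + mean(dmat(er, er))) / 2
  between <- mean(dmat(ew, er))
  expect_gt(between, within)

  # nearest-centroid style classification in embedding space: the
  # end-to-end separability property of the synthetic styles
  cw <- colMeans(ew); cr <- colMeans(er)
  allb <- rbind(ew, er)
  truth <- rep(c("walking", "running"), each = 240)
  pred <- ifelse(sqrt(rowSums(sweep(allb, 2, cw)^2)) <
                 sqrt(rowSums(sweep(allb, 2, cr)^2)), "walking", "running")
  expect_gte(mean(pred == truth), 0.9)

  expect_error(encode(conv_rbm(temporal_window = 999), walk$point_cloud),
               "temporal_window")
})

test_that("find_similar_frames equals the brute-force scan", {
  set.seed(18)
  for (case in 1:10) {
    A <- matrix(rnorm(40 * 4), 40, 4)
    B <- matrix(rnorm(35 * 4), 35, 4)
    got <- find_similar_frames(A, B, threshold = 1.5)
    want <- oracle_similar_frames(A, B, 1.5, 1, self = FALSE)
    expect_equal(got$frame_a, want$frame_a)
    expect_equal(got$frame_b, want$frame_b)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
  }
  # self-matching with exclusion
  E <- matrix(rnorm(30 * 3), 30, 3)
  got_self <- find_similar_frames(E, E, threshold = 2, exclusion = 5)
  want_self <- oracle_similar_frames(E, E, 2, 5, self = TRUE)
  expect_equal(got_self$frame_a, want_self$frame_a)
  expect_equal(got_self$frame_b, want_self$frame_b)
  # threshold 0 on distinct embeddings: empty
  expect_identical(nrow(find_similar_frames(E + 1, E, threshold = 0)), 0L)
  # infinite threshold self-match count: F(F-1)/2 minus excluded pairs
  got_all <- find_similar_frames(E, E, threshold = Inf, exclusion = 4)
  expect_identical(nrow(got_all),
                   as.integer(30 * 29 / 2 - sum(vapply(1:3, function(d) 30 - d, numeric(1)))))
  expect_error(find_similar_frames(E, matrix(0, 5, 7), 1), "dimensions differ")
})

test_that("similarity threshold is the stated quantile of pairwise distances", {
  set.seed(19)
  X <- matrix(rnorm(50 * 3), 50, 3)
  expect_equal(similarity_threshold(X, 0.15),
               unname(quantile(dist(X), 0.15)), tolerance = 1e-12)
})
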