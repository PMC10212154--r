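# Convolutional restricted Boltzmann machine over per-frame point-cloud
# slabs. Visible units form a C-channel x P-position array (default 3
# channels x 32 positions = the 96-dim point cloud); K filters of width
# w slide along the position axis (valid mode, H = P - w + 1 hidden
# positions per filter). Energy (Gaussian-visible, Bernoulli-hidden,
# unit visible variance):
#
#   E(v, h) = sum (v - b_vis)^2 / 2 - sum_k sum_p h_kp * (b_k + (W_k * v)_p)
#
# where (W_k * v)_p = sum_q sum_c W[k, q, c] v[c, p + q - 1] is the
# valid-mode correlation. `visible_type = "binary01"` keeps the same
# energy but restricts visible states to {0, 1}, which makes tiny models
# exactly enumerable; it is also the form used by the exact-likelihood
# oracle tests. An optional autoregressive history of order m adds
# linear per-unit shifts to the visible and hidden biases (m = 0
# reduces exactly to the unconditioned RBM). Training is contrastive
# divergence (CD-k).

#' Construct a convolutional RBM
#'
#' @param n_positions length of the position axis (default 32).
#' @param n_channels visible channels per frame (default 3: x, y, z).
#' @param n_filters number of convolution filters K.
#' @param kernel_width filter width w along the position axis (<=
#'   n_positions).
#' @param temporal_window frames per input slab; frames are stacked as
#'   additional channels (window T gives T * n_channels channels).
#' @param history_order autoregressive conditioning order m (0 = plain
#'   RBM).
#' @param visible_type "gaussian" (real-valued visibles) or "binary01"
#'   (visible states in {0, 1}; enumerable).
#' @param input_mode what each frame's slab holds: "positions" (the
#'   3-channel point cloud) or "dynamics" (6 channels: point cloud plus
#'   its first temporal difference, the point-cloud velocity). Frame
#'   dynamics, not static pose geometry, carry most of the style
#'   identity of cyclic motion, so "dynamics" is what the embedding
#'   pipeline uses; n_channels is derived from this mode when frames are
#'   encoded.
#' @param init_sd standard deviation of the random weight initialization.
#' @param seed RNG seed for initialization.
#' @return object of class `conv_rbm`.
#' @export
conv_rbm <- function(n_positions = 32L, n_channels = NULL, n_filters = 8L,
                     kernel_width = 9L, temporal_window = 1L,
                     history_order = 0L, visible_type = c("gaussian", "binary01"),
                     input_mode = c("positions", "dynamics"),
                     init_sd = 0.01, seed = 1L) {
  visible_type <- match.arg(visible_type)
  input_mode <- match.arg(input_mode)
  if (is.null(n_channels))
    n_channels <- if (input_mode == "dynamics") 6L else 3L
  if (kernel_width > n_positions)
    stop_mocap("kernel_width (%d) must be <= n_positions (%d)",
               kernel_width, n_positions)
  if (n_filters < 1L) stop_mocap("need at least one filter")
  if (temporal_window < 1L) stop_mocap("temporal_window must be >= 1")
  if (history_order < 0L) stop_mocap("history_order must be >= 0")
  C <- n_channels * temporal_window
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- array(stats::rnorm(n_filters * kernel_width * C, sd = init_sd),
             dim = c(n_filters, kernel_width, C))
  m <- history_order
  model <- structure(list(
    W = W,
    hidden_bias = numeric(n_filters),
    visible_bias = matrix(0, C, n_positions),
    A = if (m > 0) array(0, dim = c(m, C, n_positions)) else NULL,
    B = if (m > 0) array(0, dim = c(m, n_filters)) else NULL,
    n_positions = as.integer(n_positions),
    n_channels = as.integer(n_channels),
    n_filters = as.integer(n_filters),
    kernel_width = as.integer(kernel_width),
    temporal_window = as.integer(temporal_window),
    history_order = as.integer(m),
    visible_type = visible_type,
    input_mode = input_mode,
    pool = n_positions - kernel_width + 1L), class = "conv_rbm")
  model
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.conv_rbm <- function(x, ...) {
  cat(sprintf("<conv_rbm> %d filters x width %d over %d ch x %d pos (%s, window %d, AR %d)\n",
              x$n_filters, x$kernel_width, dim(x$W)[3], x$n_positions,
              x$visible_type, x$temporal_window, x$history_order))
  invisible(x)
}

n_hidden_positions <- function(model) model$n_positions - model$kernel_width + 1L

# dynamic bias shifts from the autoregressive history (list of past
# visible slabs, most recent first); zero when history_order = 0
history_shifts <- function(model, history = NULL) {
  m <- model$history_order
  vb <- matrix(0, nrow(model$visible_bias), ncol(model$visible_bias))
  hb <- numeric(model$n_filters)
  if (m > 0L && !is.null(history)) {
    for (l in seq_len(min(m, length(history)))) {
      vb <- vb + model$A[l, , ] * history[[l]]
      hb <- hb + model$B[l, ] * mean(history[[l]])
    }
  }
  list(visible = vb, hidden = hb)
}

as_slab <- function(model, v) {
  C <- dim(model$W)[3]
  v <- as.matrix(v)
  if (length(v) == C * model$n_positions && (nrow(v) == 1L || ncol(v) == 1L))
    v <- matrix(as.numeric(v), C, model$n_positions, byrow = TRUE)
  if (nrow(v) != C || ncol(v) != model$n_positions)
    stop_mocap("visible slab must be %d channels x %d positions", C, model$n_positions)
  v
}

# filter slice at kernel offset q as a K x C matrix (robust to K or C = 1)
filter_slice <- function(model, q) {
  matrix(model$W[, q, ], nrow = model$n_filters, ncol = dim(model$W)[3])
}

# K x H matrix of hidden pre-activations b_k + (W_k * v)_p (+ AR shift)
hidden_preactivation <- function(model, v, history = NULL) {
  v <- as_slab(model, v)
  H <- n_hidden_positions(model)
  w <- model$kernel_width
  pre <- matrix(model$hidden_bias, model$n_filters, H)
  for (q in seq_len(w))
    pre <- pre + filter_slice(model, q) %*% v[, q:(q + H - 1L), drop = FALSE]
  sh <- history_shifts(model, history)
  pre + sh$hidden
}

#' RBM energy of a (visible, hidden) configuration
#'
#' @param model a `conv_rbm`.
#' @param visible C x P visible slab (or flat vector laid out channel by
#'   channel).
#' @param hidden K x H matrix of hidden unit states.
#' @param history optional list of past visible slabs for the
#'   autoregressive variant.
#' @return scalar energy.
#' @export
rbm_energy <- function(model, visible, hidden, history = NULL) {
  v <- as_slab(model, visible)
  H <- n_hidden_positions(model)
  hidden <- as.matrix(hidden)
  if (nrow(hidden) != model$n_filters || ncol(hidden) != H)
    stop_mocap("hidden states must be %d filters x %d positions", model$n_filters, H)
  sh <- history_shifts(model, history)
  bv <- model$visible_bias + sh$visible
  pre <- hidden_preactivation(model, v, history)
  sum((v - bv)^2) / 2 - sum(hidden * pre)
}

#' Hidden-unit activation probabilities P(h = 1 | v)
#'
#' @inheritParams rbm_energy
#' @return K x H matrix of probabilities, each in (0, 1).
#' @export
hidden_conditional <- function(model, visible, history = NULL) {
  check_finite(as_slab(model, visible), "visible slab")
  sigmoid(hidden_preactivation(model, visible, history))
}

# visible conditional given hidden states: the Gaussian mean
# b_vis + sum_k W_k (transposed-conv) h_k, or Bernoulli probabilities for
# binary01 visibles
visible_mean <- function(model, hidden, history = NULL) {
  H <- n_hidden_positions(model)
  w <- model$kernel_width
  sh <- history_shifts(model, history)
  mean_v <- model$visible_bias + sh$visible
  for (q in seq_len(w)) {
    contrib <- t(filter_slice(model, q)) %*% hidden
    mean_v[, q:(q + H - 1L)] <- mean_v[, q:(q + H - 1L)] + contrib
  }
  mean_v
}

visible_conditional <- function(model, hidden, history = NULL) {
  m <- visible_mean(model, hidden, history)
  if (model$visible_type == "binary01") sigmoid(m - 0.5) else m
}

#' Exact log-likelihood of visible slabs under a tiny RBM
#'
#' Enumerates all hidden configurations (and, for the partition
#' function, all binary visible states), so it is only feasible for
#' models with a handful of units. Requires `visible_type = "binary01"`.
#'
#' @param model a tiny `conv_rbm`.
#' @param visibles list of visible slabs (or a matrix, one row each).
#' @return list with `loglik` (per slab), `log_z`.
#' @export
rbm_exact_loglik <- function(model, visibles) {
  if (model$visible_type != "binary01")
    stop_mocap("exact likelihood requires visible_type = 'binary01'")
  C <- dim(model$W)[3]; P <- model$n_positions
  nv <- C * P; nh <- model$n_filters * n_hidden_positions(model)
  if (nv > 14L || nh > 14L)
    stop_mocap("model too large to enumerate (%d visible, %d hidden units)", nv, nh)
  if (is.matrix(visibles) && !is.list(visibles))
    visibles <- lapply(seq_len(nrow(visibles)), function(i)
      matrix(visibles[i, ], C, P, byrow = TRUE))
  free_energy <- function(v) {
    pre <- hidden_preactivation(model, v)
    -sum((v - model$visible_bias)^2) / 2 + sum(log1p(exp(pre)))
  }
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), nv)))
  fe_all <- apply(states, 1, function(s) free_energy(matrix(s, C, P)))
  log_z <- logsumexp(fe_all)
  ll <- vapply(visibles, function(v) free_energy(as_slab(model, v)) - log_z,
               numeric(1))
  list(loglik = ll, log_z = log_z)
}

#' Train a convolutional RBM by contrastive divergence
#'
#' Standard CD-k: sample hidden states from P(h | v), reconstruct
#' visibles (mean-field for Gaussian visibles, Bernoulli sampling for
#' binary visibles on intermediate steps), and update weights with the
#' difference of positive and negative statistics. Deterministic given
#' `seed`.
#'
#' @param model a `conv_rbm`.
#' @param data list of visible slabs, or an F x (C * P) matrix with one
#'   flat slab per row (channel-major rows as produced by
#'   [build_point_cloud()]).
#' @param k CD steps (>= 1).
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param batch mini-batch size.
#' @param seed RNG seed.
#' @param standardized_check warn if channel means look unstandardized
#'   (|mean| > 0.5).
#' @return the trained model with attribute `recon_trace`, the per-epoch
#'   mean squared one-step reconstruction error.
#' @export
train_cd <- function(model, data, k = 1L, lr = 1e-3, epochs = 10L,
                     batch = 32L, seed = 1L, standardized_check = TRUE) {
  if (k < 1L) stop_mocap("k must be >= 1")
  C <- dim(model$W)[3]; P <- model$n_positions
  if (is.matrix(data) && !is.list(data))
    data <- lapply(seq_len(nrow(data)), function(i) matrix(data[i, ], C, P, byrow = TRUE))
  data <- lapply(data, function(v) as_slab(model, v))
  n <- length(data)
  if (standardized_check && model$visible_type == "gaussian") {
    ch_means <- rowMeans(sapply(data, rowMeans))
    if (any(abs(ch_means) > 0.5))
      warning("training data does not look standardized (|channel mean| > 0.5)",
              call. = FALSE)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  H <- n_hidden_positions(model)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    recon_err <- 0
    for (start in seq(1L, n, by = batch)) {
      ids <- idx[start:min(start + batch - 1L, n)]
      dW <- array(0, dim = dim(model$W))
      dhb <- numeric(model$n_filters)
      dvb <- matrix(0, C, P)
      for (ii in ids) {
        v0 <- data[[ii]]
        ph0 <- sigmoid(hidden_preactivation(model, v0))
        hs <- matrix(stats::rbinom(length(ph0), 1, ph0), nrow(ph0), ncol(ph0))
        vk <- v0; phk <- ph0
        for (step in seq_len(k)) {
          vk <- visible_conditional(model, hs)
          if (model$visible_type == "binary01" && step < k)
            vk <- matrix(stats::rbinom(length(vk), 1, vk), nrow(vk), ncol(vk))
          phk <- sigmoid(hidden_preactivation(model, vk))
          if (step < k)
            hs <- matrix(stats::rbinom(length(phk), 1, phk), nrow(phk), ncol(phk))
        }
        for (q in seq_len(model$kernel_width)) {
          vpos0 <- v0[, q:(q + H - 1L), drop = FALSE]
          vposk <- vk[, q:(q + H - 1L), drop = FALSE]
          dW[, q, ] <- matrix(dW[, q, ], nrow(ph0)) +
            ph0 %*% t(vpos0) - phk %*% t(vposk)
        }
        dhb <- dhb + rowSums(ph0) - rowSums(phk)
        dvb <- dvb + (v0 - vk)
        recon_err <- recon_err + mean((v0 - visible_conditional(model, ph0))^2)
      }
      nb <- length(ids)
      model$W <- model$W + lr * dW / nb
      model$hidden_bias <- model$hidden_bias + lr * dhb / nb
      model$visible_bias <- model$visible_bias + lr * dvb / nb
      if (anyNA(model$W) || any(!is.finite(model$W)))
        stop_mocap("divergence: non-finite weights at epoch %d", ep)
    }
    trace[ep] <- recon_err / n
  }
  attr(model, "recon_trace") <- trace
  model
}

#' Standardization statistics for point-cloud features
#'
#' Column means and standard deviations of the 96-dim point clouds, plus
#' the same for their first temporal differences (the point-cloud
#' velocity, computed after position standardization). Compute these on
#' the pooled training data and pass them to [encode()] and the slab
#' builder so every sequence is embedded in one common frame —
#' per-sequence statistics would silently discard the between-sequence
#' amplitude differences that distinguish styles.
#'
#' @param point_cloud F x 96 matrix (pool all training sequences).
#' @return object of class `feature_stats`.
#' @export
feature_stats <- function(point_cloud) {
  pc <- as.matrix(point_cloud)
  mu <- colMeans(pc)
  sd_ <- apply(pc, 2, stats::sd); sd_[sd_ < 1e-12] <- 1
  s <- sweep(sweep(pc, 2, mu), 2, sd_, "/")
  v <- rbind(s[2, , drop = FALSE] - s[1, , drop = FALSE], diff(s))
  vmu <- colMeans(v)
  vsd <- apply(v, 2, stats::sd); vsd[vsd < 1e-12] <- 1
  structure(list(center = mu, scale = sd_, v_center = vmu, v_scale = vsd),
            class = "feature_stats")
}

# per-frame channel block (C1 x 32 each frame) for the model's input
# mode; returns an F-long list of C1 x P matrices
frame_blocks <- function(model, pc, stats) {
  s <- sweep(sweep(pc, 2, stats$center), 2, stats$scale, "/")
  P <- model$n_positions
  if (model$input_mode == "dynamics") {
    v <- rbind(s[2, , drop = FALSE] - s[1, , drop = FALSE], diff(s))
    v <- sweep(sweep(v, 2, stats$v_center), 2, stats$v_scale, "/")
    lapply(seq_len(nrow(s)), function(f)
      rbind(matrix(s[f, ], 3, P, byrow = TRUE),
            matrix(v[f, ], 3, P, byrow = TRUE)))
  } else {
    lapply(seq_len(nrow(s)), function(f) matrix(s[f, ], 3, P, byrow = TRUE))
  }
}

#' Build training slabs for a ConvRBM from point-cloud features
#'
#' Applies the model's input mode (positions or dynamics) and temporal
#' window to an F x 96 point-cloud matrix, using shared standardization
#' statistics.
#'
#' @param model a `conv_rbm`.
#' @param features F x 96 matrix or `pose_features` object.
#' @param stats a `feature_stats` (default: computed from `features`).
#' @return list of visible slabs (C x P matrices).
#' @export
encode_slabs <- function(model, features, stats = NULL) {
  if (inherits(features, "pose_features")) features <- features$point_cloud
  pc <- as.matrix(features)
  if (is.null(stats)) stats <- feature_stats(pc)
  T_ <- model$temporal_window
  if (T_ > nrow(pc))
    stop_mocap("temporal_window (%d) exceeds frame count (%d)", T_, nrow(pc))
  blocks <- frame_blocks(model, pc, stats)
  lapply(seq_len(length(blocks) - T_ + 1L), function(f)
    do.call(rbind, blocks[f:(f + T_ - 1L)]))
}

#' Embed pose frames into the learned feature space
#'
#' Per frame: hidden conditional probabilities, then a max-pool over the
#' position axis for each filter, giving a D = K dimensional vector.
#' With `temporal_window` T > 1, frames t .. t + T - 1 are stacked as
#' channels and the embedding has F - T + 1 rows.
#'
#' @param model a trained `conv_rbm`.
#' @param features F x 96 point-cloud matrix (e.g.
#'   `pose_features(motion)$point_cloud`), or a `pose_features` object.
#' @param stats `feature_stats` of the training data; defaults to
#'   statistics of `features` itself (fine for a single sequence,
#'   wrong when comparing sequences — see [feature_stats()]).
#' @return `mocap_embedding`: an F' x K matrix with attributes.
#' @export
encode <- function(model, features, stats = NULL) {
  slabs <- encode_slabs(model, features, stats)
  out <- do.call(rbind, lapply(slabs, function(s)
    apply(hidden_conditional(model, s), 1, max)))
  structure(out, class = c("mocap_embedding", "matrix"),
            n_filters = model$n_filters)
}

#' Similarity threshold from the pairwise-distance distribution
#'
#' @param embedding a `mocap_embedding` (or plain matrix).
#' @param prob quantile of all pairwise Euclidean distances (default
#'   0.15).
#' @return scalar threshold.
#' @export
similarity_threshold <- function(embedding, prob = 0.15) {
  d <- stats::dist(unclass(embedding))
  as.numeric(stats::quantile(d, prob))
}

#' Find similar frame pairs between two embeddings
#'
#' Brute-force Euclidean scan: all pairs with distance <= threshold,
#' sorted ascending by distance. When the two embeddings are the same
#' object (self-matching), pairs closer than `exclusion` frames in time
#' are dropped and each unordered pair is reported once (frame_a <
#' frame_b).
#'
#' @param emb_a,emb_b `mocap_embedding` objects sharing the same width.
#' @param threshold distance cutoff (>= 0).
#' @param exclusion minimum temporal separation for self-matches (>= 1).
#' @return data.frame(frame_a, frame_b, distance), ascending distance.
#' @export
find_similar_frames <- function(emb_a, emb_b, threshold, exclusion = 1L) {
  A <- unclass(as.matrix(emb_a)); B <- unclass(as.matrix(emb_b))
  if (ncol(A) != ncol(B)) stop_mocap("embedding dimensions differ (%d vs %d)",
                                     ncol(A), ncol(B))
  if (exclusion < 1L) stop_mocap("exclusion must be >= 1")
  self <- isTRUE(all.equal(dim(A), dim(B))) && isTRUE(all.equal(A, B))
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  D2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  hit <- which(D <= threshold, arr.ind = TRUE)
  if (self && nrow(hit)) {
    keep <- hit[, 1] < hit[, 2] & (hit[, 2] - hit[, 1]) >= exclusion
    hit <- hit[keep, , drop = FALSE]
  }
  res <- data.frame(frame_a = as.integer(hit[, 1]),
                    frame_b = as.integer(hit[, 2]),
                    distance = D[hit])
  res[order(res$distance, res$frame_a, res$frame_b), , drop = FALSE]
}
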