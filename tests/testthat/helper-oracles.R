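# Independent oracles used by the tests. Each one recomputes a quantity
# by a different route than the implementation: explicit homogeneous
# matrices for forward kinematics, brute-force enumeration for RBM
# likelihoods, double loops for similarity scans, simple-path
# enumeration for bottleneck paths, and direct formula evaluation for
# DLT and CMC.

# ---- forward kinematics: 4x4 homogeneous-matrix chain ----------------
oracle_fk <- function(sk, frame) {
  hom <- function(R = diag(3), t = c(0, 0, 0)) {
    M <- diag(4); M[1:3, 1:3] <- R; M[1:3, 4] <- t; M
  }
  local_rot <- function(j) {
    free <- sk$dof[[j]]
    if (!length(free)) return(diag(3))
    ord <- strsplit(sk$rotation_order[j], "")[[1]]
    ang <- setNames(numeric(3), ord)
    ang[free] <- frame[mocapkit:::joint_channel_cols(sk, j)]
    R <- diag(3)
    for (ax in ord) {
      th <- ang[[ax]] * pi / 180
      Ri <- switch(ax,
        X = matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3),
        Y = matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3),
        Z = matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3))
      R <- R %*% Ri
    }
    R
  }
  J <- length(sk$name)
  M <- vector("list", J)
  M[[1]] <- hom(local_rot(1), frame[1:3])
  out <- matrix(0, J, 3)
  out[1, ] <- frame[1:3]
  for (j in seq_len(J)[-1]) {
    p <- sk$parent[j]
    M[[j]] <- M[[p]] %*% hom(t = sk$offset[j, ]) %*% hom(local_rot(j))
    out[j, ] <- (M[[p]] %*% hom(t = sk$offset[j, ]))[1:3, 4]
  }
  out
}

# random small skeleton for property tests
random_skeleton <- function(n_joints, seed) {
  set.seed(seed)
  parent <- c(NA_integer_, vapply(2:n_joints, function(j)
    sample.int(j - 1L, 1L), integer(1)))
  orders <- c("XYZ", "XZY", "YXZ", "YZX", "ZXY", "ZYX")
  rot_order <- sample(orders, n_joints, replace = TRUE)
  dof <- lapply(rot_order, function(o)
    strsplit(o, "")[[1]][seq_len(sample(3, 1))])
  dof[[1]] <- strsplit(rot_order[1], "")[[1]]   # root keeps 3 DOF
  skeleton(paste0("j", seq_len(n_joints)), parent,
           matrix(rnorm(n_joints * 3), n_joints, 3),
           rot_order, dof)
}

# ---- DLT: direct formula evaluation ----------------------------------
oracle_dlt_uv <- function(L, k1, k2, p1, p2, pp, s, P) {
  den <- L[9] * P[1] + L[10] * P[2] + L[11] * P[3] + 1
  u <- (L[1] * P[1] + L[2] * P[2] + L[3] * P[3] + L[4]) / den
  v <- (L[5] * P[1] + L[6] * P[2] + L[7] * P[3] + L[8]) / den
  x <- (u - pp[1]) / s; y <- (v - pp[2]) / s
  r2 <- x^2 + y^2
  du <- s * (x * (k1 * r2 + k2 * r2^2) + 2 * p1 * x * y + p2 * (r2 + 2 * x^2))
  dv <- s * (y * (k1 * r2 + k2 * r2^2) + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y)
  c(u + du, v + dv)
}

# independent pinhole projection (rotation matrix + intrinsics route)
oracle_pinhole_uv <- function(f_px, pp, R, pos, P) {
  pc <- R %*% (P - pos)
  c(pp[1] + f_px * pc[1] / pc[3], pp[2] + f_px * pc[2] / pc[3])
}

# ---- RBM: dense enumeration ------------------------------------------
# energy computed the long way: explicit dense weight matrix from the
# convolutional parameters, then the quadratic/bilinear form
oracle_rbm_energy <- function(model, v, h) {
  C <- dim(model$W)[3]; P <- model$n_positions
  K <- model$n_filters; w <- model$kernel_width
  H <- P - w + 1L
  E <- sum((v - model$visible_bias)^2) / 2
  for (k in seq_len(K)) for (p in seq_len(H)) {
    act <- model$hidden_bias[k]
    for (q in seq_len(w)) for (cc in seq_len(C))
      act <- act + model$W[k, q, cc] * v[cc, p + q - 1L]
    E <- E - h[k, p] * act
  }
  E
}

oracle_rbm_enumeration <- function(model) {
  C <- dim(model$W)[3]; P <- model$n_positions
  K <- model$n_filters; H <- P - model$kernel_width + 1L
  vstates <- as.matrix(expand.grid(rep(list(0:1), C * P)))
  hstates <- as.matrix(expand.grid(rep(list(0:1), K * H)))
  z_terms <- c()
  marg <- numeric(nrow(vstates))
  for (iv in seq_len(nrow(vstates))) {
    v <- matrix(vstates[iv, ], C, P)
    e_v <- vapply(seq_len(nrow(hstates)), function(ih)
      exp(-oracle_rbm_energy(model, v, matrix(hstates[ih, ], K, H))), numeric(1))
    marg[iv] <- sum(e_v)
    z_terms <- c(z_terms, e_v)
  }
  list(Z = sum(z_terms), marginal = marg, vstates = vstates)
}

# ---- similarity: brute-force double loop -----------------------------
oracle_similar_frames <- function(A, B, threshold, exclusion, self) {
  res <- NULL
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (self && (j <= i || (j - i) < exclusion)) next
    d <- sqrt(sum((A[i, ] - B[j, ])^2))
    if (d <= threshold)
      res <- rbind(res, data.frame(frame_a = i, frame_b = j, distance = d))
  }
  if (is.null(res)) return(data.frame(frame_a = integer(0), frame_b = integer(0),
                                      distance = numeric(0)))
  res[order(res$distance, res$frame_a, res$frame_b), , drop = FALSE]
}

# ---- graphs: simple-path enumeration for bottleneck criterion --------
# edges: data.frame(from, to, sim, transition); returns best achievable
# min-transition-similarity over all simple paths from any source to any
# target node (Inf-free: returns NA if unreachable)
oracle_bottleneck <- function(edges, n_nodes, sources, targets) {
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(edges)))
    adj[[edges$from[e]]] <- c(adj[[edges$from[e]]], e)
  best <- -Inf
  found <- FALSE
  visit <- function(node, cur_min, seen) {
    if (node %in% targets) {
      found <<- TRUE
      if (cur_min > best) best <<- cur_min
    }
    for (e in adj[[node]]) {
      nxt <- edges$to[e]
      if (seen[nxt]) next
      m <- if (edges$transition[e]) min(cur_min, edges$sim[e]) else cur_min
      seen2 <- seen; seen2[nxt] <- TRUE
      visit(nxt, m, seen2)
    }
  }
  for (s in sources) {
    seen <- rep(FALSE, n_nodes); seen[s] <- TRUE
    visit(s, Inf, seen)
  }
  if (!found) NA_real_ else best
}

# strongly-connected components by repeated forward/backward reachability
oracle_scc <- function(edges, n_nodes) {
  reach <- function(start, adj) {
    seen <- rep(FALSE, n_nodes); frontier <- start; seen[start] <- TRUE
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.na(nxt) & !seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    which(seen)
  }
  fwd <- lapply(seq_len(n_nodes), function(i) edges$to[edges$from == i])
  bwd <- lapply(seq_len(n_nodes), function(i) edges$from[edges$to == i])
  comp <- rep(0L, n_nodes); cid <- 0L
  for (i in seq_len(n_nodes)) {
    if (comp[i] != 0L) next
    cid <- cid + 1L
    members <- intersect(reach(i, fwd), reach(i, bwd))
    comp[members] <- cid
  }
  comp
}

# a plausible two-harmonic gait-like waveform (degrees, one cycle)
gait_signal <- function(n = 101) {
  t <- seq(0, 1, length.out = n)
  30 * sin(2 * pi * t) + 10 * sin(4 * pi * t + 0.7)
}

# ---- CMC: direct textbook evaluation ---------------------------------
oracle_cmc <- function(y) {
  M <- nrow(y); N <- ncol(y)
  ybar_t <- colMeans(y); ybar <- mean(y)
  num <- 0
  for (m in seq_len(M)) for (t in seq_len(N)) num <- num + (y[m, t] - ybar_t[t])^2
  den <- 0
  for (m in seq_len(M)) for (t in seq_len(N)) den <- den + (y[m, t] - ybar)^2
  ratio <- (num / (N * (M - 1))) / (den / (M * N - 1))
  if (ratio > 1) NA_real_ else sqrt(1 - ratio)
}

# build a tiny dense binary-visible RBM (3 visible, 2 hidden): a
# conv_rbm with kernel_width == n_positions has exactly one hidden
# position per filter, i.e. a dense RBM
tiny_rbm <- function(seed = 1, sd = 0.5) {
  m <- conv_rbm(n_positions = 3, n_channels = 1, n_filters = 2,
                kernel_width = 3, visible_type = "binary01",
                init_sd = sd, seed = seed)
  set.seed(seed + 100)
  m$hidden_bias <- rnorm(2, sd = 0.3)
  m$visible_bias <- matrix(rnorm(3, sd = 0.3), 1, 3)
  m
}

# exact sampler for a tiny enumerable RBM
sample_tiny_rbm <- function(model, n, seed) {
  enum <- oracle_rbm_enumeration(model)
  probs <- enum$marginal / enum$Z
  set.seed(seed)
  idx <- sample.int(nrow(enum$vstates), n, replace = TRUE, prob = probs)
  lapply(idx, function(i) matrix(enum$vstates[i, ], 1, 3))
}
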