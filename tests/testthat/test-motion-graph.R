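# motion graph construction, bottleneck transition selection, blending
# and synthesis

make_two_styles <- function(n_frames = 80, seed = 1) {
  sk <- gen_skeleton(32, seed = seed)
  list(sk = sk,
       motions = list(
         walking = gen_motion(sk, "walking", n_frames = n_frames, seed = seed + 1),
         running = gen_motion(sk, "running", n_frames = n_frames, seed = seed + 2)))
}

test_that("chain graph: no candidates, one sequence", {
  st <- make_two_styles(25, seed = 2)
  mg <- build_graph(st$motions["walking"])
  expect_identical(as.integer(igraph::vcount(mg$graph)), 25L)
  expect_identical(sum(igraph::E(mg$graph)$type == "transition"), 0L)
  expect_identical(as.integer(igraph::ecount(mg$graph)), 24L)
  expect_true(all(igraph::E(mg$graph)$similarity == 1))
})

test_that("transition edges carry similarity 1/(1+distance)", {
  st <- make_two_styles(30, seed = 3)
  cand <- data.frame(seq_a = "walking", frame_a = c(10L, 20L),
                     seq_b = "running", frame_b = c(5L, 15L),
                     distance = c(0, 0.25))
  mg <- build_graph(st$motions, cand)
  sims <- sort(unique(igraph::E(mg$graph)$similarity[
    igraph::E(mg$graph)$type == "transition"]))
  expect_equal(sims, c(1 / 1.25, 1), tolerance = 1e-12)
  expect_error(build_graph(st$motions,
                           data.frame(seq_a = "walking", frame_a = 99L,
                                      seq_b = "running", frame_b = 1L,
                                      distance = 0.1)),
               "out of range")
})

test_that("strongly-connected structure matches the reachability oracle", {
  for (case in 1:5) {
    st <- make_two_styles(12, seed = 10 + case)
    set.seed(30 + case)
    n_cand <- 4
    cand <- data.frame(
      seq_a = sample(c("walking", "running"), n_cand, replace = TRUE),
      frame_a = sample(12, n_cand, replace = TRUE),
      seq_b = sample(c("walking", "running"), n_cand, replace = TRUE),
      frame_b = sample(12, n_cand, replace = TRUE),
      distance = runif(n_cand, 0, 0.5))
    mg <- build_graph(st$motions, cand)
    g <- mg$graph
    ed <- igraph::as_edgelist(g)
    edges <- data.frame(from = as.integer(ed[, 1]), to = as.integer(ed[, 2]))
    want <- oracle_scc(edges, igraph::vcount(g))
    got <- igraph::components(g, mode = "strong")$membership
    # same partition (label-invariant comparison)
    expect_identical(length(unique(want)), length(unique(got)))
    expect_true(all(tapply(got, want, function(x) length(unique(x))) == 1))
  }
})

test_that("select_transition picks the highest-similarity edge", {
  st <- make_two_styles(20, seed = 4)
  cand <- data.frame(seq_a = "walking", frame_a = c(5L, 12L),
                     seq_b = "running", frame_b = c(8L, 3L),
                     distance = c(1 / 0.7 - 1, 1 / 0.9 - 1))  # sims 0.7, 0.9
  mg <- build_graph(st$motions, cand)
  p <- select_transition(mg, "walking", "running")
  expect_true(p$available)
  expect_equal(p$bottleneck, 0.9, tolerance = 1e-9)
  used <- p$edges[p$edges$type == "transition", ]
  expect_identical(used$frame_a, 12L)

  # from == to: empty path
  p_same <- select_transition(mg, "walking", "walking")
  expect_true(p_same$available)
  expect_null(p_same$edges)

  # disconnected styles: explicit no-transition result, not an error
  mg0 <- build_graph(st$motions)
  p0 <- select_transition(mg0, "walking", "running")
  expect_false(p0$available)
  expect_error(select_transition(mg0, "walking", "flying"), "unknown sequence")
})

test_that("bottleneck path equals exhaustive simple-path enumeration", {
  for (case in 1:8) {
    st <- make_two_styles(6, seed = 40 + case)
    set.seed(60 + case)
    n_cand <- sample(2:5, 1)
    cand <- data.frame(
      seq_a = sample(c("walking", "running"), n_cand, replace = TRUE),
      frame_a = sample(6, n_cand, replace = TRUE),
      seq_b = sample(c("walking", "running"), n_cand, replace = TRUE),
      frame_b = sample(6, n_cand, replace = TRUE),
      distance = round(runif(n_cand, 0, 2), 3))
    mg <- build_graph(st$motions, cand)
    g <- mg$graph
    ed <- igraph::as_edgelist(g)
    edges <- data.frame(from = as.integer(ed[, 1]), to = as.integer(ed[, 2]),
                        sim = igraph::E(g)$similarity,
                        transition = igraph::E(g)$type == "transition")
    src <- unique(mg$membership$node[mg$membership$seq == "walking"])
    dst <- unique(mg$membership$node[mg$membership$seq == "running"])
    want <- oracle_bottleneck(edges, igraph::vcount(g), src, dst)
    p <- select_transition(mg, "walking", "running")
    if (is.na(want)) {
      expect_false(p$available)
    } else {
      expect_true(p$available)
      got <- if (is.infinite(want)) 1 else want
      expect_equal(p$bottleneck, got, tolerance = 1e-9)
    }
  }
})

test_that("blend respects endpoints, linear root, slerp midpoint", {
  st <- make_two_styles(40, seed = 5)
  walk <- st$motions$walking
  cfg <- transition_config(30)

  # idempotent: blending a segment with itself reproduces it
  seg <- motion_sequence(st$sk, walk$frames[1:35, ], walk$frame_rate)
  self_blend <- blend_transition(seg, seg, cfg)
  expect_equal(self_blend$frames, seg$frames[1:30, ], tolerance = 1e-9)

  # linear root midpoint
  sk1 <- skeleton("root", NA, matrix(0, 1, 3), "ZXY", list(c("Z", "X", "Y")))
  a <- motion_sequence(sk1, matrix(rep(c(0, 0, 0, 0, 0, 0), 3), 3, byrow = TRUE), 30)
  b <- motion_sequence(sk1, matrix(rep(c(2, 0, 0, 0, 0, 0), 3), 3, byrow = TRUE), 30)
  mid <- blend_transition(a, b, transition_config(3))
  expect_equal(unname(mid$frames[2, 1:3]), c(1, 0, 0), tolerance = 1e-12)

  # slerp midpoint of a 0 -> 90 degree Z rotation is 45 degrees
  b2 <- motion_sequence(sk1, matrix(rep(c(0, 0, 0, 90, 0, 0), 3), 3, byrow = TRUE), 30)
  mid2 <- blend_transition(a, b2, transition_config(3))
  expect_equal(unname(mid2$frames[2, 4]), 45, tolerance = 1e-9)

  # blend quaternions stay unit: all output rows produce orthonormal rotations
  run <- st$motions$running
  segA <- motion_sequence(st$sk, walk$frames[1:30, ], walk$frame_rate)
  segB <- motion_sequence(st$sk, run$frames[1:30, ], run$frame_rate)
  bl <- blend_transition(segA, segB, cfg)
  expect_equal(bl$frames[1, ], walk$frames[1, ], tolerance = 1e-15)
  expect_equal(bl$frames[30, ], run$frames[30, ], tolerance = 1e-15)
  for (f in c(2, 15, 29)) {
    R <- euler_to_rotmat("ZXY", bl$frames[f, 4:6])
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
  }
  expect_error(blend_transition(segA, motion_sequence(sk1, a$frames, 30), cfg),
               "skeleton mismatch")
  expect_error(transition_config(1), "window")
})

test_that("synthesize: endpoint contract, frame count, continuity", {
  st <- make_two_styles(100, seed = 6)
  cand <- data.frame(seq_a = "walking", frame_a = 50L,
                     seq_b = "running", frame_b = 30L, distance = 0.1)
  mg <- build_graph(st$motions, cand)
  p <- select_transition(mg, "walking", "running")
  # absolute-root mode: endpoints equal the inputs exactly
  out <- synthesize(mg, p, st$motions, transition_config(30), root_align = "none")
  walkF <- st$motions$walking$frames; runF <- st$motions$running$frames
  expect_identical(nrow(out$frames), 49L + 30L + (100L - 59L))
  expect_equal(out$frames[1, ], walkF[1, ], tolerance = 1e-15)
  expect_equal(out$frames[nrow(out$frames), ], runF[100, ], tolerance = 1e-15)
  # velocity mode: same posture channels, root differs only by a rigid offset
  outv <- synthesize(mg, p, st$motions, transition_config(30))
  expect_equal(outv$frames[, -(1:3)], out$frames[, -(1:3)], tolerance = 1e-12)
  n <- nrow(outv$frames)
  tail_off <- sweep(outv$frames[(n - 10):n, 1:3], 2,
                    outv$frames[n, 1:3] - runF[100, 1:3])
  expect_equal(tail_off, out$frames[(n - 10):n, 1:3], tolerance = 1e-9)

  # no transition edges -> source unchanged
  p_same <- select_transition(mg, "walking", "walking")
  out_same <- synthesize(mg, p_same, st$motions)
  expect_identical(out_same$frames, walkF)

  # inputs not mutated
  expect_identical(st$motions$walking$frames, walkF)

  # root-displacement continuity across 5 random style pairs
  for (case in 1:5) {
    st2 <- make_two_styles(90, seed = 70 + case)
    set.seed(90 + case)
    cand2 <- data.frame(seq_a = "walking", frame_a = sample(31:59, 1),
                        seq_b = "running", frame_b = sample(11:39, 1),
                        distance = runif(1, 0, 0.3))
    mg2 <- build_graph(st2$motions, cand2)
    out2 <- synthesize(mg2, select_transition(mg2, "walking", "running"),
                       st2$motions, transition_config(30))
    max_disp <- function(fr) max(sqrt(rowSums(diff(fr[, 1:3])^2)))
    bound <- 1.05 * max(max_disp(st2$motions$walking$frames),
                        max_disp(st2$motions$running$frames))
    expect_lte(max_disp(out2$frames), bound)
  }
})
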