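# Motion graph: nodes group frames with mutually similar postures
# (connected components of the candidate-pair graph; isolated frames are
# singleton nodes), temporal edges chain consecutive frames of each
# source sequence with similarity 1, and each candidate pair contributes
# a transition edge with similarity 1 / (1 + distance). Transition paths
# are chosen by the bottleneck criterion (maximize the minimum
# transition-edge similarity), and transitions are synthesized with a
# linearly weighted blend window (root lerp + per-joint quaternion
# slerp).

#' Build a motion graph
#'
#' @param sequences named list of `motion_sequence` objects (names are
#'   the sequence/style ids).
#' @param candidates data.frame with columns seq_a, frame_a, seq_b,
#'   frame_b, distance — candidate similar-frame pairs (e.g. from
#'   [find_similar_frames()]).
#' @return object of class `motion_graph`: list with the igraph `graph`,
#'   a `membership` table mapping (seq, frame) to node id, and the
#'   sequence names.
#' @export
build_graph <- function(sequences, candidates = NULL) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop_mocap("sequences must be a named list")
  nF <- vapply(sequences, function(s) nrow(s$frames), integer(1))
  if (is.null(candidates))
    candidates <- data.frame(seq_a = character(0), frame_a = integer(0),
                             seq_b = character(0), frame_b = integer(0),
                             distance = numeric(0))
  for (i in seq_len(nrow(candidates))) {
    for (side in c("a", "b")) {
      s <- candidates[[paste0("seq_", side)]][i]
      f <- candidates[[paste0("frame_", side)]][i]
      if (!s %in% names(sequences))
        stop_mocap("candidate %d references unknown sequence '%s'", i, s)
      if (f < 1L || f > nF[[s]])
        stop_mocap("candidate %d: frame %d out of range for sequence '%s' (F=%d)",
                   i, f, s, nF[[s]])
    }
  }
  key <- function(s, f) paste0(s, ":", f)
  all_keys <- unlist(lapply(names(sequences), function(s) key(s, seq_len(nF[[s]]))))
  # union-find over same-sequence candidate pairs -> posture groups; a
  # node is a group of frames of ONE sequence. Cross-sequence pairs stay
  # as transition edges between distinct nodes (merging them would let
  # paths hop sequences through a node without crossing any transition
  # edge, breaking the bottleneck-similarity criterion).
  parent <- seq_along(all_keys)
  names(parent) <- all_keys
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(nrow(candidates))) {
    if (candidates$seq_a[i] != candidates$seq_b[i]) next
    a <- find(match(key(candidates$seq_a[i], candidates$frame_a[i]), all_keys))
    b <- find(match(key(candidates$seq_b[i], candidates$frame_b[i]), all_keys))
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_along(all_keys), find, integer(1))
  node_id <- match(comp, unique(comp))
  membership <- data.frame(
    seq = sub(":[0-9]+$", "", all_keys),
    frame = as.integer(sub("^.*:", "", all_keys)),
    node = node_id, stringsAsFactors = FALSE)

  g <- igraph::make_empty_graph(n = length(unique(comp)), directed = TRUE)
  ed_from <- integer(0); ed_to <- integer(0)
  ed_sim <- numeric(0); ed_type <- character(0)
  ed_sa <- character(0); ed_fa <- integer(0)
  ed_sb <- character(0); ed_fb <- integer(0)
  node_of <- function(s, f) membership$node[match(key(s, f), all_keys)]
  for (s in names(sequences)) {
    if (nF[[s]] > 1L) {
      from <- vapply(seq_len(nF[[s]] - 1L), function(f) node_of(s, f), integer(1))
      to <- vapply(seq_len(nF[[s]] - 1L) + 1L, function(f) node_of(s, f), integer(1))
      keep <- from != to
      ed_from <- c(ed_from, from[keep]); ed_to <- c(ed_to, to[keep])
      ed_sim <- c(ed_sim, rep(1, sum(keep)))
      ed_type <- c(ed_type, rep("temporal", sum(keep)))
      ed_sa <- c(ed_sa, rep(s, sum(keep))); ed_fa <- c(ed_fa, which(keep))
      ed_sb <- c(ed_sb, rep(s, sum(keep))); ed_fb <- c(ed_fb, which(keep) + 1L)
    }
  }
  for (i in seq_len(nrow(candidates))) {
    na <- node_of(candidates$seq_a[i], candidates$frame_a[i])
    nb <- node_of(candidates$seq_b[i], candidates$frame_b[i])
    sim <- 1 / (1 + candidates$distance[i])
    # both directions: a similar-posture pair permits transition either way
    ed_from <- c(ed_from, na, nb); ed_to <- c(ed_to, nb, na)
    ed_sim <- c(ed_sim, sim, sim)
    ed_type <- c(ed_type, "transition", "transition")
    ed_sa <- c(ed_sa, candidates$seq_a[i], candidates$seq_b[i])
    ed_fa <- c(ed_fa, candidates$frame_a[i], candidates$frame_b[i])
    ed_sb <- c(ed_sb, candidates$seq_b[i], candidates$seq_a[i])
    ed_fb <- c(ed_fb, candidates$frame_b[i], candidates$frame_a[i])
  }
  if (length(ed_from)) {
    g <- igraph::add_edges(g, rbind(ed_from, ed_to))
    igraph::E(g)$similarity <- ed_sim
    igraph::E(g)$type <- ed_type
    igraph::E(g)$seq_a <- ed_sa; igraph::E(g)$frame_a <- ed_fa
    igraph::E(g)$seq_b <- ed_sb; igraph::E(g)$frame_b <- ed_fb
  }
  structure(list(graph = g, membership = membership,
                 sequences = names(sequences), n_frames = nF),
            class = "motion_graph")
}

#' @export
print.motion_graph <- function(x, ...) {
  nt <- if (igraph::ecount(x$graph))
    sum(igraph::E(x$graph)$type == "transition") else 0L
  cat(sprintf("<motion_graph> %d nodes, %d edges (%d transition), sequences: %s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), nt,
              paste(x$sequences, collapse = ", ")))
  invisible(x)
}

#' Select a transition path between two styles
#'
#' Among all graph paths from any frame of `from_style` to any frame of
#' `to_style`, picks one maximizing the bottleneck (minimum) similarity
#' over its transition edges; ties are broken by fewer transition edges,
#' then by earliest source frame. Temporal edges (similarity 1) never
#' constrain the bottleneck.
#'
#' @param mg a `motion_graph`.
#' @param from_style,to_style sequence ids present in the graph.
#' @return object of class `transition_path`: list with `available`,
#'   `edges` (data.frame of the path's edges), `bottleneck`. When
#'   `from_style == to_style` the path is empty; when no path exists,
#'   `available` is FALSE.
#' @export
select_transition <- function(mg, from_style, to_style) {
  for (s in c(from_style, to_style))
    if (!s %in% mg$sequences) stop_mocap("unknown sequence '%s'", s)
  empty <- structure(list(available = TRUE, edges = NULL, bottleneck = 1,
                          from = from_style, to = to_style),
                     class = "transition_path")
  if (from_style == to_style) return(empty)
  g <- mg$graph
  src_nodes <- mg$membership$node[mg$membership$seq == from_style]
  dst_nodes <- unique(mg$membership$node[mg$membership$seq == to_style])
  # order source nodes by earliest from-style frame (tie-break rule)
  src_order <- order(mg$membership$frame[mg$membership$seq == from_style])
  src_seq <- unique(src_nodes[src_order])
  sims <- if (igraph::ecount(g)) igraph::E(g)$similarity else numeric(0)
  types <- if (igraph::ecount(g)) igraph::E(g)$type else character(0)
  thresholds <- sort(unique(c(1, sims[types == "transition"])), decreasing = TRUE)
  for (thr in thresholds) {
    keep <- which(types == "temporal" | sims >= thr)
    sub <- igraph::subgraph_from_edges(g, igraph::E(g)[keep],
                                       delete.vertices = FALSE)
    dmat <- igraph::distances(sub, v = src_seq, to = dst_nodes, mode = "out",
                              weights = as.numeric(igraph::E(sub)$type == "transition"))
    if (!any(is.finite(dmat))) next
    best_cost <- min(dmat[is.finite(dmat)])
    # earliest source frame achieving the minimal transition-edge count
    si <- which(apply(dmat, 1, function(r) any(is.finite(r) & r == best_cost)))[1]
    ti <- which(is.finite(dmat[si, ]) & dmat[si, ] == best_cost)[1]
    sp <- igraph::shortest_paths(sub, from = src_seq[si], to = dst_nodes[ti],
                                 mode = "out",
                                 weights = as.numeric(igraph::E(sub)$type == "transition"),
                                 output = "epath")$epath[[1]]
    eids <- as.integer(sp)
    edges <- data.frame(
      from_node = as.integer(igraph::ends(sub, sp)[, 1]),
      to_node = as.integer(igraph::ends(sub, sp)[, 2]),
      type = igraph::E(sub)$type[eids],
      similarity = igraph::E(sub)$similarity[eids],
      seq_a = igraph::E(sub)$seq_a[eids], frame_a = igraph::E(sub)$frame_a[eids],
      seq_b = igraph::E(sub)$seq_b[eids], frame_b = igraph::E(sub)$frame_b[eids],
      stringsAsFactors = FALSE)
    trans <- edges$type == "transition"
    bottleneck <- if (any(trans)) min(edges$similarity[trans]) else 1
    return(structure(list(available = TRUE, edges = edges,
                          bottleneck = bottleneck,
                          from = from_style, to = to_style),
                     class = "transition_path"))
  }
  structure(list(available = FALSE, edges = NULL, bottleneck = NA_real_,
                 from = from_style, to = to_style,
                 reason = "no transition available"),
            class = "transition_path")
}

#' @export
print.transition_path <- function(x, ...) {
  if (!x$available) {
    cat(sprintf("<transition_path> %s -> %s: no transition available\n", x$from, x$to))
  } else if (is.null(x$edges)) {
    cat(sprintf("<transition_path> %s -> %s: empty (already there)\n", x$from, x$to))
  } else {
    cat(sprintf("<transition_path> %s -> %s: %d edges, bottleneck similarity %.4f\n",
                x$from, x$to, nrow(x$edges), x$bottleneck))
  }
  invisible(x)
}

#' Transition blend configuration
#'
#' @param window blend length in frames (>= 2; default 30).
#' @param rotation_blend "slerp" (quaternion geodesic, default) or
#'   "lerp_angles" (per-channel linear with shortest-arc wrapping).
#' @return list of class `transition_config`.
#' @export
transition_config <- function(window = 30L, rotation_blend = c("slerp", "lerp_angles")) {
  rotation_blend <- match.arg(rotation_blend)
  window <- as.integer(window)
  if (window < 2L) stop_mocap("blend window must be >= 2 frames")
  structure(list(window = window, root_blend = "linear",
                 rotation_blend = rotation_blend),
            class = "transition_config")
}

# blend the rotation channels of one joint between two frames at weight t
blend_joint_rotation <- function(sk, j, row_a, row_b, t, mode) {
  cols <- joint_channel_cols(sk, j)
  if (!length(cols)) return(numeric(0))
  a <- row_a[cols]; b <- row_b[cols]
  if (mode == "lerp_angles" || length(sk$dof[[j]]) < 3L) {
    # reduced-DOF joints can't represent arbitrary blended rotations in
    # their channels; blend per channel along the shortest arc
    return(a + t * wrap_angle_deg(b - a))
  }
  ord <- sk$rotation_order[j]
  qa <- quat_from_rotmat(euler_to_rotmat(ord, a[match(parse_axis_order(ord), sk$dof[[j]])]))
  qb <- quat_from_rotmat(euler_to_rotmat(ord, b[match(parse_axis_order(ord), sk$dof[[j]])]))
  q <- quat_slerp(qa, qb, t)
  ang <- rotmat_to_euler(rotmat_from_quat(q), ord)
  ang[match(sk$dof[[j]], parse_axis_order(ord))]
}

#' Blend two motion segments over a linear window
#'
#' Frame i (0-based) of the output uses weight w_i = i / (W - 1): root
#' translation is interpolated linearly, joint rotations by quaternion
#' slerp (per joint, in the joint's declared Euler order). The first
#' output frame equals the first source frame exactly and the last
#' equals the W-th target frame exactly. Segments shorter than the
#' window are extended by clamping their last frame.
#'
#' @param source,target `motion_sequence` segments on the same skeleton
#'   and frame rate.
#' @param config a `transition_config`.
#' @return a `motion_sequence` of exactly `window` frames.
#' @export
blend_transition <- function(source, target, config = transition_config()) {
  sk <- source$skeleton
  if (!same_skeleton(sk, target$skeleton))
    stop_mocap("skeleton mismatch between source and target segments")
  if (source$frame_rate != target$frame_rate)
    stop_mocap("frame-rate mismatch: %g vs %g", source$frame_rate, target$frame_rate)
  W <- config$window
  clamp_rows <- function(m, n) {
    idx <- pmin(seq_len(n), nrow(m))
    m[idx, , drop = FALSE]
  }
  Sa <- clamp_rows(source$frames, W)
  Sb <- clamp_rows(target$frames, W)
  out <- matrix(0, W, ncol(Sa))
  colnames(out) <- colnames(source$frames)
  for (i in seq_len(W)) {
    t <- (i - 1) / (W - 1)
    row_a <- Sa[i, ]; row_b <- Sb[i, ]
    row <- row_a
    row[1:3] <- (1 - t) * row_a[1:3] + t * row_b[1:3]
    for (j in seq_along(sk$name))
      row[joint_channel_cols(sk, j)] <-
        blend_joint_rotation(sk, j, row_a, row_b, t, config$rotation_blend)
    out[i, ] <- row
  }
  out[1, ] <- Sa[1, ]      # endpoint contracts are exact by construction
  out[W, ] <- Sb[W, ]
  motion_sequence(sk, out, source$frame_rate)
}

#' Synthesize a motion along a transition path
#'
#' Concatenates, for each transition edge of the path in order: the
#' current sequence's frames up to the transition frame, a blended
#' window starting at the transition frame of the source and the matched
#' frame of the target, then continues in the target sequence. A path
#' with no transition edges returns the source sequence unchanged.
#'
#' `root_align` controls the root-translation channels of the splice.
#' With `"velocity"` (default) the blended window interpolates the two
#' streams' root *velocities* and integrates them, and the downstream
#' frames are rigidly translated to continue the integrated trajectory;
#' this guarantees that the frame-to-frame root displacement of the
#' output never exceeds the larger of the two inputs' displacements
#' (motion is translation-invariant, so the rigid offset is
#' immaterial). With `"none"` root positions are blended in absolute
#' coordinates, so the output ends exactly on the target's absolute
#' trajectory, at the cost of a transient root-speed overshoot
#' proportional to the absolute offset between the matched frames.
#' Rotation channels are identical under both modes.
#'
#' @param mg a `motion_graph`.
#' @param path a `transition_path` from [select_transition()].
#' @param sequences the named list of sequences the graph was built from.
#' @param config a `transition_config`.
#' @param root_align "velocity" or "none" (see Details).
#' @return a `motion_sequence`.
#' @export
synthesize <- function(mg, path, sequences, config = transition_config(),
                       root_align = c("velocity", "none")) {
  root_align <- match.arg(root_align)
  if (!inherits(path, "transition_path")) stop_mocap("path must be a transition_path")
  if (!path$available) stop_mocap("no transition available for %s -> %s", path$from, path$to)
  cur_seq <- path$from
  if (is.null(path$edges) || !any(path$edges$type == "transition"))
    return(sequences[[cur_seq]])
  rates <- unique(vapply(sequences, function(s) s$frame_rate, numeric(1)))
  if (length(rates) > 1L)
    stop_mocap("frame-rate mismatch across sequences: %s", paste(rates, collapse = ", "))
  trans_edges <- path$edges[path$edges$type == "transition", , drop = FALSE]
  W <- config$window
  sk <- sequences[[cur_seq]]$skeleton
  out <- NULL
  cur_start <- 1L
  cur_off <- c(0, 0, 0)   # rigid root offset of the current stream
  for (e in seq_len(nrow(trans_edges))) {
    sA <- trans_edges$seq_a[e]; fA <- trans_edges$frame_a[e]
    sB <- trans_edges$seq_b[e]; fB <- trans_edges$frame_b[e]
    if (sA != cur_seq)
      stop_mocap("path edge %d starts in '%s' but current sequence is '%s'", e, sA, cur_seq)
    seqA <- sequences[[sA]]; seqB <- sequences[[sB]]
    if (fA >= cur_start + 1L) {
      pre <- seqA$frames[cur_start:(fA - 1L), , drop = FALSE]
      pre[, 1:3] <- sweep(pre[, 1:3, drop = FALSE], 2, cur_off, "+")
      out <- rbind(out, pre)
    }
    segA <- motion_sequence(sk, seqA$frames[fA:nrow(seqA$frames), , drop = FALSE],
                            seqA$frame_rate)
    segB <- motion_sequence(sk, seqB$frames[fB:nrow(seqB$frames), , drop = FALSE],
                            seqB$frame_rate)
    blend <- blend_transition(segA, segB, config)
    bl <- blend$frames
    if (root_align == "velocity") {
      SA <- segA$frames[pmin(seq_len(W), nrow(segA$frames)), 1:3, drop = FALSE]
      SB <- segB$frames[pmin(seq_len(W), nrow(segB$frames)), 1:3, drop = FALSE]
      r <- matrix(0, W, 3)
      r[1, ] <- SA[1, ] + cur_off
      for (i in seq_len(W - 1L)) {
        w <- (i - 1) / (W - 1)
        r[i + 1L, ] <- r[i, ] + (1 - w) * (SA[i + 1L, ] - SA[i, ]) +
          w * (SB[i + 1L, ] - SB[i, ])
      }
      bl[, 1:3] <- r
      cur_off <- r[W, ] - SB[W, ]
    } else {
      bl[1, 1:3] <- bl[1, 1:3] + cur_off   # keep the incoming stream rigid
      cur_off <- c(0, 0, 0)
    }
    out <- rbind(out, bl)
    cur_seq <- sB
    cur_start <- min(fB + W, nrow(seqB$frames) + 1L)
  }
  last <- sequences[[cur_seq]]
  if (cur_start <= nrow(last$frames)) {
    post <- last$frames[cur_start:nrow(last$frames), , drop = FALSE]
    post[, 1:3] <- sweep(post[, 1:3, drop = FALSE], 2, cur_off, "+")
    out <- rbind(out, post)
  }
  motion_sequence(sk, out, last$frame_rate)
}
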