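# BVH reading and writing (standard HIERARCHY/MOTION layout). Angles are
# kept in degrees, matching the file format; rotation orders and free
# DOFs are taken from each joint's CHANNELS line. Line endings (LF/CRLF)
# are normalized on read.

#' Read a motion file
#'
#' Parses a BVH file, or an ASF skeleton plus AMC motion pair (CMU
#' dialect), into the package's data model.
#'
#' @param path path to the BVH or ASF file.
#' @param format "bvh" or "asf_amc".
#' @param amc_path path to the AMC file (required for "asf_amc").
#' @return list with elements `skeleton` and `motion`.
#' @export
read_motion <- function(path, format = c("bvh", "asf_amc"), amc_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_mocap("file not found: %s", path)
  if (format == "bvh") return(read_bvh(path))
  if (is.null(amc_path)) stop_mocap("asf_amc format needs `amc_path`")
  read_asf_amc(path, amc_path)
}

read_lines_norm <- function(path) {
  x <- readLines(path, warn = FALSE)
  gsub("\r", "", x, fixed = TRUE)
}

read_bvh <- function(path) {
  lines <- read_lines_norm(path)
  toks <- unlist(strsplit(trimws(lines[nzchar(trimws(lines))]), "[ \t]+"))
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  nxt <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(what) {
    t <- nxt()
    if (is.na(t) || t != what) stop_mocap("BVH parse error: expected '%s', got '%s'", what, t)
    t
  }
  if (toupper(nxt()) != "HIERARCHY") stop_mocap("not a BVH file: missing HIERARCHY")

  name <- character(); parent <- integer(); offset <- NULL
  rot_order <- character(); dof <- list(); has_pos <- logical()

  parse_joint <- function(parent_idx, kw) {
    jname <- nxt()
    expect("{")
    expect("OFFSET")
    off <- as.numeric(c(nxt(), nxt(), nxt()))
    if (any(is.na(off))) stop_mocap("BVH parse error: bad OFFSET for joint '%s'", jname)
    expect("CHANNELS")
    nch <- as.integer(nxt())
    ch <- character(nch)
    for (i in seq_len(nch)) ch[i] <- nxt()
    rot <- sub("rotation$", "", ch[grepl("rotation$", ch, ignore.case = TRUE)])
    posch <- grepl("position$", ch, ignore.case = TRUE)
    if (any(posch) && !is.na(parent_idx))
      stop_mocap("BVH joint '%s': position channels only supported on the root", jname)
    j <- length(name) + 1L
    name[j] <<- jname; parent[j] <<- parent_idx
    offset <<- rbind(offset, off)
    dof[[j]] <<- toupper(rot)
    rot_order[j] <<- if (length(rot)) paste(toupper(rot), collapse = "") else "ZXY"
    has_pos[j] <<- any(posch)
    repeat {
      t <- nxt()
      if (is.na(t)) stop_mocap("BVH parse error: unexpected end inside joint '%s'", jname)
      if (t == "}") break
      if (toupper(t) %in% c("JOINT", "ROOT")) {
        parse_joint(j, t)
      } else if (toupper(t) == "END") {
        nxt()           # "Site"
        expect("{")
        expect("OFFSET"); nxt(); nxt(); nxt()
        expect("}")
      } else stop_mocap("BVH parse error: unexpected token '%s' in joint '%s'", t, jname)
    }
    j
  }
  if (toupper(peek()) != "ROOT") stop_mocap("BVH parse error: expected ROOT")
  nxt()
  parse_joint(NA_integer_, "ROOT")

  sk <- skeleton(name, parent, offset, rot_order, dof)

  expect("MOTION")
  expect("Frames:")
  F <- as.integer(nxt())
  t1 <- nxt(); t2 <- nxt()   # "Frame" "Time:"
  if (!(toupper(t1) == "FRAME" && toupper(t2) == "TIME:"))
    stop_mocap("BVH parse error: missing 'Frame Time:' line")
  ft <- as.numeric(nxt())
  if (!is.finite(ft) || ft <= 0) stop_mocap("BVH parse error: bad frame time")
  nchan_file <- sum(lengths(dof)) + 3L * sum(has_pos)
  vals <- suppressWarnings(as.numeric(toks[pos:length(toks)]))
  if (anyNA(vals) || length(vals) != F * nchan_file) {
    bad <- which(is.na(vals))[1]
    stop_mocap("BVH parse error: expected %d frames x %d channels, got %d values%s",
               F, nchan_file, length(vals),
               if (anyNA(vals)) sprintf(" (non-numeric near frame %d)",
                                        ceiling(bad / nchan_file)) else "")
  }
  raw <- matrix(vals, nrow = F, ncol = nchan_file, byrow = TRUE)

  # map file columns (per-joint, positions first on root) to model layout
  frames <- matrix(0, F, n_channels(sk))
  col <- 1L
  for (j in seq_along(name)) {
    if (has_pos[j]) { frames[, 1:3] <- raw[, col:(col + 2L)]; col <- col + 3L }
    nd <- length(dof[[j]])
    if (nd) {
      frames[, joint_channel_cols(sk, j)] <- raw[, col:(col + nd - 1L), drop = FALSE]
      col <- col + nd
    }
  }
  colnames(frames) <- channel_names(sk)
  list(skeleton = sk, motion = motion_sequence(sk, frames, 1 / ft))
}

#' Write a motion sequence as BVH
#'
#' Emits standard HIERARCHY/MOTION sections; the root carries
#' Xposition/Yposition/Zposition channels followed by its rotation
#' channels, other joints carry rotation channels only. Leaf joints get a
#' zero-offset End Site.
#'
#' @param sk a `skeleton`.
#' @param motion a matching `motion_sequence`.
#' @param path output file path.
#' @param digits numeric precision for motion lines (10 keeps the 1e-6 round-trip contract for channel magnitudes up to 1e4).
#' @return `path`, invisibly.
#' @export
write_motion <- function(sk, motion, path, digits = 10) {
  validate_skeleton(sk)
  if (!same_skeleton(sk, motion$skeleton) ||
      ncol(motion$frames) != n_channels(sk))
    stop_mocap("write_motion: motion does not match skeleton")
  validate_motion(motion)
  children <- lapply(seq_along(sk$name), function(j) which(sk$parent == j))
  out <- character(0)
  emit <- function(s) out[[length(out) + 1L]] <<- s
  fmt <- function(x) formatC(x, format = "g", digits = digits)

  write_joint <- function(j, depth) {
    ind <- strrep("\t", depth)
    kw <- if (is.na(sk$parent[j])) "ROOT" else "JOINT"
    emit(paste0(ind, kw, " ", sk$name[j]))
    emit(paste0(ind, "{"))
    emit(paste0(ind, "\tOFFSET ", paste(fmt(sk$offset[j, ]), collapse = " ")))
    rot <- paste0(sk$dof[[j]], "rotation")
    ch <- if (is.na(sk$parent[j])) c("Xposition", "Yposition", "Zposition", rot) else rot
    emit(paste0(ind, "\tCHANNELS ", length(ch), " ", paste(ch, collapse = " ")))
    kids <- children[[j]]
    if (length(kids)) {
      for (k in kids) write_joint(k, depth + 1L)
    } else {
      emit(paste0(ind, "\tEnd Site"))
      emit(paste0(ind, "\t{"))
      emit(paste0(ind, "\t\tOFFSET 0 0 0"))
      emit(paste0(ind, "\t}"))
    }
    emit(paste0(ind, "}"))
  }
  emit("HIERARCHY")
  write_joint(1L, 0L)
  emit("MOTION")
  emit(paste0("Frames: ", nrow(motion$frames)))
  emit(paste0("Frame Time: ", formatC(1 / motion$frame_rate, format = "g", digits = 10)))
  for (f in seq_len(nrow(motion$frames))) {
    row <- c(motion$frames[f, 1:3],
             unlist(lapply(seq_along(sk$name), function(j)
               motion$frames[f, joint_channel_cols(sk, j)])))
    emit(paste(fmt(row), collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}
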