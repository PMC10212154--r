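# ASF/AMC reading, restricted to the CMU dialect (:DEGREES units, dof
# lines rx/ry/rz, hierarchy block). Each bone becomes one joint; a
# joint's offset is its parent bone's direction * length (the root's
# children sit at the root). Bone-local axis orientations, limits and
# documentation blocks are parsed but ignored: this keeps the data model
# a plain offset hierarchy, which is all downstream features use.

read_asf_amc <- function(asf_path, amc_path) {
  sk_info <- parse_asf(asf_path)
  sk <- sk_info$skeleton
  frames <- parse_amc(amc_path, sk, sk_info$root_order)
  list(skeleton = sk, motion = motion_sequence(sk, frames, sk_info$frame_rate))
}

parse_asf <- function(path) {
  lines <- read_lines_norm(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  txt <- trimws(lines)
  sect <- function(name) which(txt == paste0(":", name))

  # units: CMU files use angle deg
  deg <- TRUE
  ui <- sect("units")
  if (length(ui)) {
    nexts <- grep("^:", txt); endu <- c(nexts[nexts > ui[1]], length(txt) + 1L)[1] - 1L
    ub <- txt[(ui[1] + 1L):endu]
    if (any(grepl("^angle\\s+rad", ub))) deg <- FALSE
  }
  if (!deg) stop_mocap("ASF parse error: only degree units supported (CMU dialect)")

  # root block
  ri <- sect("root")
  if (!length(ri)) stop_mocap("ASF parse error: missing :root section")
  root_order <- c("TX", "TY", "TZ", "RX", "RY", "RZ")
  nexts <- grep("^:", txt); endr <- c(nexts[nexts > ri[1]], length(txt) + 1L)[1] - 1L
  for (l in txt[(ri[1] + 1L):endr]) {
    if (grepl("^order", l))
      root_order <- toupper(strsplit(l, "\\s+")[[1]][-1])
  }

  name <- "root"; parent <- NA_integer_
  offset <- matrix(0, 1, 3)
  rot_order <- "XYZ"
  dof <- list(c("X", "Y", "Z"))
  bone_dir <- list(root = c(0, 0, 0)); bone_len <- list(root = 0)
  bone_dof <- list(root = c("X", "Y", "Z"))
  bone_axis_order <- list(root = "XYZ")

  bi <- sect("bonedata")
  if (length(bi)) {
    i <- bi[1] + 1L
    while (i <= length(txt) && !grepl("^:", txt[i])) {
      if (txt[i] == "begin") {
        b <- list(dof = character(0), axis_order = "XYZ")
        i <- i + 1L
        while (i <= length(txt) && txt[i] != "end") {
          parts <- strsplit(txt[i], "\\s+")[[1]]
          key <- parts[1]
          if (key == "name") b$name <- parts[2]
          if (key == "direction") b$direction <- as.numeric(parts[2:4])
          if (key == "length") b$length <- as.numeric(parts[2])
          if (key == "axis") b$axis_order <- toupper(parts[length(parts)])
          if (key == "dof")
            b$dof <- toupper(sub("^r", "", parts[-1]))
          i <- i + 1L
        }
        if (is.null(b$name)) stop_mocap("ASF parse error: bone without a name")
        bone_dir[[b$name]] <- b$direction %||% c(0, 0, 0)
        bone_len[[b$name]] <- b$length %||% 0
        bone_dof[[b$name]] <- b$dof
        bone_axis_order[[b$name]] <- b$axis_order
      }
      i <- i + 1L
    }
  }

  hi <- sect("hierarchy")
  if (!length(hi)) stop_mocap("ASF parse error: missing :hierarchy section")
  i <- hi[1] + 1L
  while (i <= length(txt) && txt[i] != "begin") i <- i + 1L
  i <- i + 1L
  while (i <= length(txt) && txt[i] != "end") {
    parts <- strsplit(txt[i], "\\s+")[[1]]
    pname <- parts[1]
    pidx <- match(pname, name)
    if (is.na(pidx))
      stop_mocap("ASF parse error: hierarchy references unknown parent joint '%s'", pname)
    for (child in parts[-1]) {
      if (!child %in% names(bone_dir))
        stop_mocap("ASF parse error: hierarchy references unknown bone '%s'", child)
      if (child %in% name)
        stop_mocap("ASF parse error: bone '%s' appears twice in hierarchy (cycle?)", child)
      j <- length(name) + 1L
      name[j] <- child; parent[j] <- pidx
      offset <- rbind(offset, bone_dir[[pname]] * bone_len[[pname]])
      d <- bone_dof[[child]]
      ao <- parse_axis_order(bone_axis_order[[child]])
      # rotation order: the bone's axis order restricted doesn't matter for
      # locked axes; keep the declared 3-axis order, dof as declared
      rot_order[j] <- paste(ao, collapse = "")
      dof[[j]] <- if (length(d)) d else character(0)
    }
    i <- i + 1L
  }
  list(skeleton = skeleton(name, parent, offset, rot_order, dof),
       root_order = root_order, frame_rate = 120)
}

parse_amc <- function(path, sk, root_order) {
  txt <- trimws(read_lines_norm(path))
  txt <- txt[nzchar(txt) & !grepl("^#", txt)]
  txt <- txt[!grepl("^:", txt)]   # :FULLY-SPECIFIED, :DEGREES
  is_frame <- grepl("^[0-9]+$", txt)
  starts <- which(is_frame)
  if (!length(starts)) stop_mocap("AMC parse error: no frames found")
  F <- length(starts)
  frames <- matrix(0, F, n_channels(sk))
  colnames(frames) <- channel_names(sk)
  bounds <- c(starts, length(txt) + 1L)
  for (f in seq_len(F)) {
    rows <- txt[(bounds[f] + 1L):(bounds[f + 1L] - 1L)]
    for (l in rows) {
      parts <- strsplit(l, "\\s+")[[1]]
      jname <- parts[1]
      vals <- as.numeric(parts[-1])
      if (jname == sk$name[1]) {
        if (length(vals) != length(root_order))
          stop_mocap("AMC parse error: frame %d root has %d values, expected %d",
                     f, length(vals), length(root_order))
        for (q in seq_along(root_order)) {
          ch <- root_order[q]
          if (ch %in% c("TX", "TY", "TZ"))
            frames[f, match(ch, c("TX", "TY", "TZ"))] <- vals[q]
          else {
            ax <- sub("^R", "", ch)
            pos <- match(ax, sk$dof[[1]])
            if (!is.na(pos)) frames[f, 3L + pos] <- vals[q]
          }
        }
      } else {
        j <- match(jname, sk$name)
        if (is.na(j))
          stop_mocap("AMC parse error: frame %d names unknown joint '%s'", f, jname)
        cols <- joint_channel_cols(sk, j)
        if (length(vals) != length(cols))
          stop_mocap("AMC parse error: frame %d joint '%s' has %d values, expected %d",
                     f, jname, length(vals), length(cols))
        frames[f, cols] <- vals
      }
    }
  }
  frames
}
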