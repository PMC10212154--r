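# Agreement analysis of paired joint-angle waveforms: mean-shift
# (vertical) alignment and the coefficient of multiple correlation
# (CMC), the standard waveform-similarity statistic of gait analysis.
# The within-day Kadaba form is used: with M curves y_m(t), t = 1..N,
#
#   CMC = sqrt(1 - [ S_mt (y_mt - ybar_t)^2 / (N (M - 1)) ]
#                / [ S_mt (y_mt - ybar)^2  / (M N - 1)  ])
#
# where ybar_t is the across-curve mean at sample t and ybar the grand
# mean. Values near 1 mean the curves agree in shape and magnitude; when
# the variance ratio exceeds 1 the statistic is undefined (the curves
# disagree more than the waveform varies) and is reported as such.

#' Construct a joint-angle waveform set
#'
#' @param joint joint name (e.g. "hip").
#' @param plane anatomical plane: "flexion_extension",
#'   "abduction_adduction" or "varus_valgus".
#' @param system measurement-system label.
#' @param trials T x N matrix: T time-normalized angle curves (degrees).
#' @return object of class `joint_angle_waveform`.
#' @export
joint_angle_waveform <- function(joint, plane = c("flexion_extension",
                                                  "abduction_adduction",
                                                  "varus_valgus"),
                                 system, trials) {
  plane <- match.arg(plane)
  trials <- as.matrix(trials)
  if (nrow(trials) < 1L || ncol(trials) < 2L)
    stop_mocap("waveform needs >= 1 trial and >= 2 samples")
  check_finite(trials, "angle curves")
  structure(list(joint = joint, plane = plane, system = system,
                 trials = trials),
            class = "joint_angle_waveform")
}

#' @export
print.joint_angle_waveform <- function(x, ...) {
  cat(sprintf("<joint_angle_waveform> %s/%s [%s]: %d trials x %d samples\n",
              x$joint, x$plane, x$system, nrow(x$trials), ncol(x$trials)))
  invisible(x)
}

#' Time-normalize a curve to a fixed number of samples
#'
#' Linear interpolation onto an even grid over the cycle (standard
#' 0-100% gait-cycle normalization with n = 101).
#'
#' @param y numeric vector or T x N matrix (rows resampled).
#' @param n number of output samples (default 101).
#' @return vector or matrix with n columns.
#' @export
time_normalize <- function(y, n = 101L) {
  resample <- function(v) {
    stats::approx(seq(0, 1, length.out = length(v)), v,
                  xout = seq(0, 1, length.out = n))$y
  }
  if (is.matrix(y)) t(apply(y, 1, resample)) else resample(y)
}

#' Vertically align a curve to another curve's mean
#'
#' Translates `curve_a` up or down so its mean equals `curve_b`'s mean;
#' the shape (deviations from its own mean) is unchanged.
#'
#' @param curve_a,curve_b numeric vectors of equal length (degrees).
#' @return shifted copy of `curve_a`.
#' @export
mean_shift_align <- function(curve_a, curve_b) {
  if (length(curve_a) != length(curve_b))
    stop_mocap("curve length mismatch: %d vs %d", length(curve_a), length(curve_b))
  curve_a - mean(curve_a) + mean(curve_b)
}

#' Coefficient of multiple correlation of a set of curves
#'
#' @param y M x N matrix: M >= 2 curves measuring the same waveform at N
#'   >= 2 time-normalized samples.
#' @return numeric CMC in [0, 1], or `NA` with attributes
#'   `defined = FALSE` and `reason` when the statistic is undefined
#'   (variance ratio > 1, or zero total variance).
#' @export
cmc <- function(y) {
  y <- as.matrix(y)
  M <- nrow(y); N <- ncol(y)
  if (M < 2L) stop_mocap("CMC needs at least 2 curves")
  if (N < 2L) stop_mocap("CMC needs at least 2 samples")
  ybar_t <- colMeans(y)
  ybar <- mean(y)
  within <- sum(sweep(y, 2, ybar_t)^2) / (N * (M - 1))
  total <- sum((y - ybar)^2) / (M * N - 1)
  if (total <= .Machine$double.eps) {
    return(structure(NA_real_, defined = FALSE,
                     reason = "zero total variance (all curves constant and equal)"))
  }
  ratio <- within / total
  if (ratio > 1) {
    return(structure(NA_real_, defined = FALSE,
                     reason = sprintf("variance ratio %.3f > 1", ratio)))
  }
  structure(sqrt(1 - ratio), defined = TRUE)
}

#' Compare two measurement systems joint by joint
#'
#' For every (joint, plane) present in both systems: optionally
#' mean-shift-align each of system A's trials to system B's grand mean,
#' stack the matched trials of both systems, and compute the CMC.
#' Joints present in only one system are listed as skipped.
#'
#' @param system_a,system_b lists of `joint_angle_waveform` objects.
#' @param align apply mean-shift alignment of A's trials to B's grand
#'   mean first (default TRUE).
#' @return data.frame of class `cmc_report`: joint, plane, cmc, defined,
#'   reason, n_trials, n_samples, skipped.
#' @export
compare_systems <- function(system_a, system_b, align = TRUE) {
  key <- function(w) paste(w$joint, w$plane, sep = "/")
  ka <- vapply(system_a, key, character(1))
  kb <- vapply(system_b, key, character(1))
  all_keys <- union(ka, kb)
  rows <- lapply(all_keys, function(k) {
    ia <- match(k, ka); ib <- match(k, kb)
    parts <- strsplit(k, "/")[[1]]
    if (is.na(ia) || is.na(ib)) {
      return(data.frame(joint = parts[1], plane = parts[2], cmc = NA_real_,
                        defined = FALSE, reason = "present in one system only",
                        n_trials = NA_integer_, n_samples = NA_integer_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    A <- system_a[[ia]]$trials; B <- system_b[[ib]]$trials
    if (ncol(A) != ncol(B))
      stop_mocap("%s: sample counts differ (%d vs %d); time-normalize first",
                 k, ncol(A), ncol(B))
    if (align) {
      gm <- mean(B)
      A <- t(apply(A, 1, function(tr) tr - mean(tr) + gm))
    }
    stacked <- rbind(A, B)
    v <- cmc(stacked)
    data.frame(joint = parts[1], plane = parts[2], cmc = as.numeric(v),
               defined = isTRUE(attr(v, "defined")),
               reason = attr(v, "reason") %||% "",
               n_trials = nrow(stacked), n_samples = ncol(stacked),
               skipped = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cmc_report", "data.frame")
  out
}
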