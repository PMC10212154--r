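#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Wrap angle differences into (-180, 180] degrees
#'
#' @param d numeric vector of angle differences in degrees.
#' @return wrapped differences; -180 maps to +180.
#' @keywords internal
wrap_angle_deg <- function(d) {
  w <- ((d + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stop_mocap <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_mocap("non-finite values in %s", what)
  invisible(x)
}
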