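#' Wrap angles to (-pi, pi]
#'
#' All angular quantities in the package are radians wrapped to `(-pi, pi]`;
#' degrees appear only at I/O boundaries (printed summaries, tuning widths).
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped to `(-pi, pi]`.
#' @export
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
wrap_angle <- function(x) {
  y <- x %% (2 * pi)
  i <- which(y > pi)
  y[i] <- y[i] - 2 * pi
  y
}

#' Circular distance between two angles on the ring
#'
#' Unsigned circular distance, i.e. the length of the shorter arc between two
#' directions. Used for the Gaussian recurrent kernel and the directional
#' sensory input of the head-direction attractor.
#'
#' @param phi_i,phi_j Angles in radians (recycled against each other).
#' @return Distances in `[0, pi]`.
#' @export
#' @examples
#' ring_distance(0, pi)
#' ring_distance(0.1, 2 * pi - 0.1)
ring_distance <- function(phi_i, phi_j) {
  stopifnot(all(is.finite(phi_i)), all(is.finite(phi_j)))
  abs(wrap_angle(phi_i - phi_j))
}

#' Circular mean of angles
#'
#' @param x Angles in radians.
#' @param w Optional nonnegative weights.
#' @return The circular mean in `(-pi, pi]`, or `NA` if the resultant vanishes.
#' @keywords internal
circ_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  z <- sum(w * exp(1i * x))
  if (Mod(z) < .Machine$double.eps * length(x)) return(NA_real_)
  Arg(z)
}

#' Circular variance of angles
#'
#' One minus the mean resultant length, in `[0, 1]`.
#'
#' @param x Angles in radians.
#' @return Circular variance.
#' @keywords internal
circ_var <- function(x) {
  1 - Mod(mean(exp(1i * x)))
}

deg <- function(x) x * 180 / pi
rad <- function(x) x * pi / 180
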