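#' Deterministic test fixtures with known ground truth
#'
#' Small constructed inputs (bump fields, sweep-direction sequences,
#' model-generated autocorrelograms) whose expected outputs are known in
#' closed form, so decoders and metrics are testable without running the full
#' simulator.
#'
#' @name fixtures
NULL

#' Wrapped Gaussian bump field
#'
#' On the ring (`center` a scalar) returns a length-`n` rate vector; on the
#' torus (`center` length 2) an `n x n` field. The decoder ground truth is
#' `center`.
#'
#' @param center Bump center: angle (ring) or phase pair (torus), radians.
#' @param width Gaussian width, radians (> 0).
#' @param n Lattice size per dimension.
#' @return Rate vector or field with peak value 1.
#' @export
make_bump_field <- function(center, width, n) {
  stopifnot(width > 0, n >= 4)
  phi <- 2 * pi * (seq_len(n) - 1) / n
  if (length(center) == 1) {
    exp(-ring_distance(phi, center)^2 / (2 * width^2))
  } else {
    gx <- exp(-wrap_angle(phi - center[1])^2 / (2 * width^2))
    gy <- exp(-wrap_angle(phi - center[2])^2 / (2 * width^2))
    outer(gx, gy)
  }
}

#' Deterministic sweep-direction sequences
#'
#' @param pattern `"alternating"` (score 1), `"constant"` (score 0) or
#'   `"custom"` (angles supplied in `angles`).
#' @param amplitude Angle amplitude, radians (alternating/constant).
#' @param n Sequence length (>= 3).
#' @param angles Custom angle vector, radians.
#' @return Numeric vector of sweep directions in `(-pi, pi]`.
#' @export
make_sweep_sequence <- function(pattern = c("alternating", "constant", "custom"),
                                amplitude = pi / 9, n = 11, angles = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(n >= 3)
  switch(pattern,
         alternating = amplitude * (-1)^(seq_len(n) - 1),
         constant = rep(amplitude, n),
         custom = {
           if (is.null(angles)) stop("custom pattern needs 'angles'")
           wrap_angle(angles)
         })
}

#' Autocorrelogram synthesized from the skipping model
#'
#' Forward-evaluates [skipping_model] on the standard 5 ms lag grid, with
#' optional Gaussian noise, for parameter-recovery tests of
#' [fit_skipping_model].
#'
#' @param par Named parameters (within the fit bounds; see
#'   [fit_skipping_model]).
#' @param noise_sd Gaussian noise SD (0 = noiseless).
#' @param seed Seed for the noise.
#' @param window,binwidth Lag grid, seconds.
#' @return An `acg` object.
#' @export
make_acg_from_model <- function(par, noise_sd = 0, seed = 1,
                                window = 0.5, binwidth = 0.005) {
  nb <- 2 * round(window / binwidth) + 1
  lag <- (seq_len(nb) - (nb + 1) / 2) * binwidth
  val <- skipping_model(lag, par)
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    val <- val + stats::rnorm(nb, 0, noise_sd)
  }
  structure(list(lag = lag, value = val, counts = NULL), class = "acg")
}
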