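#' Bump center on the torus
#'
#' Per-dimension circular mean of the phase lattice weighted by rates (the
#' center of mass of the activity bump in phase space). Errors when the field
#' has no coherent bump: the mean resultant length in either dimension falls
#' below `tol`.
#'
#' @param r An `n x n` nonnegative rate field; rows index the first phase
#'   coordinate.
#' @param phi Optional phase lattice values (defaults to `n` equally spaced
#'   phases in `[0, 2*pi)`).
#' @param tol Coherence threshold on the mean resultant length.
#' @return Length-2 phase coordinate in `[0, 2*pi)`.
#' @export
bump_center_torus <- function(r, phi = NULL, tol = 0.1) {
  if (is.null(phi)) phi <- 2 * pi * (seq_len(nrow(r)) - 1) / nrow(r)
  out <- bump_center_torus_or_na(r, phi, tol)
  if (anyNA(out)) {
    stop("undefined bump center: no coherent bump on the torus (resultant below ",
         tol, ")", call. = FALSE)
  }
  out
}

bump_center_torus_or_na <- function(r, phi, tol = 0.1) {
  s <- sum(r)
  if (s <= 0) return(c(NA_real_, NA_real_))
  zx <- sum(rowSums(r) * exp(1i * phi))
  zy <- sum(colSums(r) * exp(1i * phi))
  if (Mod(zx) / s < tol || Mod(zy) / s < tol) return(c(NA_real_, NA_real_))
  c(Arg(zx), Arg(zy)) %% (2 * pi)
}

#' Invert the phase mapping along a continuous phase trace
#'
#' The map from physical position to torus phase is many-to-one in reverse.
#' The inverse is resolved by the consistency (nearest-continuation) rule:
#' the initial sample is assigned the lattice preimage closest to `anchor_z`,
#' and every subsequent sample continues from its predecessor by unwrapping
#' the componentwise phase increments (always the nearest preimage, valid
#' because per-step phase changes are below half a period). The decoded path
#' may leave the arena.
#'
#' @param phase A `T x 2` matrix of phase coordinates in `[0, 2*pi)`. Rows
#'   with `NA` (incoherent samples) are carried through as `NA` and bridged
#'   by unwrapping across the gap.
#' @param lambda Grid spacing, metres.
#' @param anchor_z Physical location used to pick the initial preimage.
#' @return A `T x 2` matrix of physical positions, metres.
#' @export
phase_to_physical <- function(phase, lambda, anchor_z) {
  stopifnot(is.matrix(phase), ncol(phase) == 2, lambda > 0,
            length(anchor_z) == 2)
  ok <- !is.na(phase[, 1]) & !is.na(phase[, 2])
  if (!any(ok)) stop("phase trace has no coherent samples")
  idx <- which(ok)
  ph <- phase[idx, , drop = FALSE]
  dph <- diff(ph)
  if (nrow(dph) > 0) {
    dph <- wrap_angle(dph)
    bad <- which(abs(dph) >= pi - 1e-9, arr.ind = TRUE)
    if (length(bad)) {
      stop("ambiguous phase trace: per-step phase jump >= pi at step ",
           idx[bad[1, 1] + 1], call. = FALSE)
    }
  }
  # sheared ("axis") coordinates with period lambda
  u0 <- ph[1, ] * lambda / (2 * pi)
  Winv <- w_trans_inv()
  # initial preimage: integer lattice offsets minimizing distance to anchor_z
  base <- round(drop(w_trans() %*% anchor_z) / lambda)
  ks <- expand.grid(k1 = base[1] + (-2:2), k2 = base[2] + (-2:2))
  cand <- t(Winv %*% (t(as.matrix(ks)) * lambda + u0))
  pick <- which.min((cand[, 1] - anchor_z[1])^2 + (cand[, 2] - anchor_z[2])^2)
  u_start <- u0 + as.numeric(ks[pick, ]) * lambda
  u <- matrix(u_start, 1)
  if (nrow(dph) > 0) {
    cum <- apply(dph * lambda / (2 * pi), 2, cumsum)
    if (!is.matrix(cum)) cum <- matrix(cum, nrow = 1)
    u <- rbind(u, sweep(cum, 2, u_start, "+"))
  }
  z <- t(Winv %*% t(u))
  out <- matrix(NA_real_, nrow(phase), 2)
  out[idx, ] <- z
  out
}

#' Decode internal direction and internal location from a coupled run
#'
#' Combines the HD internal-direction trace with the torus-to-physical inverse
#' mapping of one grid module's bump-center trace.
#'
#' @param run A `coupled_run` from [run_coupled].
#' @param module Index of the grid module to decode (default 1).
#' @param anchor Physical anchor for the inverse mapping (default: the
#'   trajectory start).
#' @return A data frame of class `decoded_track` with columns `t`,
#'   `internal_dir`, `loc_x`, `loc_y`, `phase_x`, `phase_y`, `coherent`.
#' @export
decode_track <- function(run, module = 1, anchor = NULL) {
  stopifnot(inherits(run, "coupled_run"))
  mod <- run$modules[[module]]
  if (is.null(anchor)) anchor <- c(run$traj$x[1], run$traj$y[1])
  loc <- phase_to_physical(mod$center, mod$params$lambda, anchor)
  out <- data.frame(t = run$t,
                    internal_dir = run$hd$center,
                    loc_x = loc[, 1], loc_y = loc[, 2],
                    phase_x = mod$center[, 1], phase_y = mod$center[, 2],
                    coherent = !is.na(mod$center[, 1]) & !is.na(run$hd$center))
  attr(out, "lambda") <- mod$params$lambda
  attr(out, "dt") <- attr(run$traj, "dt")
  class(out) <- c("decoded_track", "data.frame")
  out
}

#' Write a decoded track as CSV
#' @param track A `decoded_track`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_decoded_track <- function(track, file) {
  utils::write.csv(as.data.frame(track), file, row.names = FALSE)
  invisible(file)
}
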