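#' Segment a decoded track into per-theta-cycle sweeps
#'
#' Theta cycles are delimited by zero crossings of the septal theta phase
#' (`omega_theta * t mod 2*pi`); the septal drive is the model's clock. Within
#' each complete cycle the sweep vector is the decoded internal location at
#' its maximum displacement from the concurrent animal position, minus the
#' animal position at that moment (sweeps return toward the animal within the
#' cycle, so the tip -- not the cycle end -- defines the sweep). The sweep
#' direction `alpha` is the signed angle from the instantaneous movement
#' direction to the sweep vector (left of travel positive). The HD sweep is
#' summarized by `peak_dir_offset`, the signed offset of the internal
#' direction from the head direction at the moment of peak HD population rate
#' in the cycle.
#'
#' Cycles containing incoherent decoded samples, or whose median speed is
#' below `v_min` (immobility), are marked invalid and excluded from
#' aggregates.
#'
#' @param track A `decoded_track` from [decode_track].
#' @param traj The [trajectory] that drove the run.
#' @param theta_phase Theta phase series aligned with `track$t` (radians in
#'   `[0, 2*pi)`).
#' @param hd_pop_rate Optional HD population-rate series (for the rate peak);
#'   defaults to constant, in which case the offset is taken mid-cycle.
#' @param v_min Immobility threshold, m/s (default 0.02).
#' @param forward_band Unsigned angle (radians) below which a sweep is
#'   classified `forward` rather than `left`/`right`.
#' @return A data frame of class `sweep_records`, one row per complete theta
#'   cycle: `cycle_index`, `alpha` (rad), `length` (m), `length_phase`
#'   (phase rad), `peak_dir_offset` (rad), `side`, `valid`.
#' @export
segment_sweeps <- function(track, traj, theta_phase, hd_pop_rate = NULL,
                           v_min = 0.02, forward_band = pi / 18) {
  stopifnot(nrow(track) == nrow(traj), length(theta_phase) == nrow(track))
  cyc <- cumsum(c(0, diff(theta_phase) < -pi)) # new cycle at each phase wrap
  ids <- unique(cyc)
  # drop the (possibly partial) first and last cycles
  ids <- ids[ids != cyc[1] & ids != cyc[length(cyc)]]
  if (length(ids) < 2) stop("need at least 2 full theta cycles")
  if (is.null(hd_pop_rate)) hd_pop_rate <- rep(1, nrow(track))
  # movement direction from position increments
  mv_dir <- atan2(c(diff(traj$y), NA), c(diff(traj$x), NA))
  recs <- lapply(ids, function(id) {
    s <- which(cyc == id)
    dx <- track$loc_x[s] - traj$x[s]
    dy <- track$loc_y[s] - traj$y[s]
    disp <- sqrt(dx^2 + dy^2)
    valid <- all(track$coherent[s]) && stats::median(traj$v[s]) >= v_min &&
      all(is.finite(disp))
    if (!valid) {
      return(data.frame(cycle_index = id, alpha = NA_real_, length = NA_real_,
                        length_phase = NA_real_, peak_dir_offset = NA_real_,
                        side = NA_character_, valid = FALSE))
    }
    tip <- which.max(disp)
    mdir <- mv_dir[s[tip]]
    if (is.na(mdir)) mdir <- traj$theta_hd[s[tip]]
    alpha <- wrap_angle(atan2(dy[tip], dx[tip]) - mdir)
    len <- disp[tip]
    pk <- which.max(hd_pop_rate[s])
    pdo <- wrap_angle(track$internal_dir[s[pk]] - traj$theta_hd[s[pk]])
    side <- if (abs(alpha) < forward_band) "forward"
            else if (alpha > 0) "left" else "right"
    lambda <- attr(track, "lambda")
    data.frame(cycle_index = id, alpha = alpha, length = len,
               length_phase = if (is.null(lambda)) NA_real_
                              else len * 2 * pi / lambda,
               peak_dir_offset = pdo, side = side, valid = TRUE)
  })
  out <- do.call(rbind, recs)
  # a sweep of zero length has no direction
  zero_len <- out$valid & out$length < .Machine$double.eps^0.5
  out$valid[zero_len] <- FALSE
  out$alpha[zero_len] <- NA_real_
  class(out) <- c("sweep_records", "data.frame")
  out
}

#' Sweep alternation score
#'
#' For each interior sweep `i` of the direction sequence, with
#' `a_i = alpha_i - alpha_(i-1)` and `b_i = alpha_(i+1) - alpha_i`, the local
#' score is `|a_i - b_i| / (2 * max(|a_i|, |b_i|))`; the overall score is the
#' mean of the local scores. Angle differences are plain (non-wrapped)
#' differences of sweep angles expressed in `(-pi, pi]`. The score lies in
#' `[0, 1]`: 1 for perfect left-right alternation, 0 for a constant sequence
#' (a triplet of three identical angles scores 0 by convention).
#'
#' @param alphas Numeric vector of at least 3 sweep directions, radians in
#'   `(-pi, pi]` (`NA`s removed first).
#' @return The alternation score in `[0, 1]`.
#' @export
#' @examples
#' alternation_score(c(20, -20, 20) * pi / 180)   # 1
#' alternation_score(c(10, 10, 10) * pi / 180)    # 0
#' alternation_score(c(30, -10, 20) * pi / 180)   # 0.875
alternation_score <- function(alphas) {
  alphas <- alphas[!is.na(alphas)]
  if (length(alphas) < 3) stop("need at least 3 sweep directions")
  a <- diff(alphas)[-(length(alphas) - 1)]
  b <- diff(alphas)[-1]
  mx <- pmax(abs(a), abs(b))
  s <- ifelse(mx == 0, 0, abs(a - b) / (2 * mx))
  mean(s)
}

#' Aggregate sweep statistics
#'
#' Mean unsigned sweep angle (and mean unsigned HD peak offset), circular
#' variance of the signed sweep angle, mean sweep length (metres and phase
#' units), and the alternation score, over the valid records.
#'
#' @param records A `sweep_records` data frame from [segment_sweeps].
#' @return A list of class `sweep_stats` with fields `n`,
#'   `mean_abs_alpha_deg`, `var_alpha`, `mean_length_m`, `mean_length_phase`,
#'   `mean_abs_peak_dir_offset_deg`, `alternation`.
#' @export
sweep_stats <- function(records) {
  v <- records[records$valid, , drop = FALSE]
  if (nrow(v) < 3) stop("insufficient data: fewer than 3 valid sweep records")
  structure(list(
    n = nrow(v),
    mean_abs_alpha_deg = deg(mean(abs(v$alpha))),
    var_alpha = circ_var(v$alpha),
    mean_length_m = mean(v$length),
    mean_length_phase = mean(v$length_phase),
    mean_abs_peak_dir_offset_deg = deg(mean(abs(v$peak_dir_offset))),
    alternation = alternation_score(v$alpha)
  ), class = "sweep_stats")
}

#' @export
print.sweep_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<sweep_stats> %d cycles\n",
    "  location sweep angle  mean|alpha| = %.1f deg (circ. var %.3f)\n",
    "  direction peak offset mean        = %.1f deg\n",
    "  sweep length          mean        = %.3f m (%.2f phase rad)\n",
    "  alternation score                 = %.3f\n"),
    x$n, x$mean_abs_alpha_deg, x$var_alpha,
    x$mean_abs_peak_dir_offset_deg, x$mean_length_m, x$mean_length_phase,
    x$alternation))
  invisible(x)
}
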