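# Shared helpers: small networks and constructed decoded tracks.

rad <- function(x) x * pi / 180
deg <- function(x) x * 180 / pi

small_hd <- function(...) hd_params(N = 64, ...)

small_grid <- function(...) grid_params(n_side = 16, ...)

# A decoded track that departs from the animal's path by `amp` metres
# perpendicular-left of movement at the middle of every theta cycle.
make_perp_left_track <- function(speed = 0.3, duration = 2, dt = 1e-3,
                                 amp = 0.1, omega_theta = 2 * pi * 9) {
  traj <- make_straight_run(speed, 0, duration, dt)
  phase <- (omega_theta * traj$t) %% (2 * pi)
  # triangular displacement profile peaking mid-cycle
  bump <- amp * pmax(0, 1 - abs(phase - pi) / (pi / 2))
  track <- data.frame(t = traj$t,
                      internal_dir = traj$theta_hd,
                      loc_x = traj$x,
                      loc_y = traj$y + bump,
                      phase_x = 0, phase_y = 0,
                      coherent = TRUE)
  attr(track, "lambda") <- 0.4
  attr(track, "dt") <- dt
  class(track) <- c("decoded_track", "data.frame")
  list(track = track, traj = traj, phase = phase)
}

# Spatial autocorrelogram-based gridness score (standard rotate-correlate on
# an annulus; positive for six-fold-symmetric rate maps).
gridness_score <- function(map) {
  n1 <- nrow(map); n2 <- ncol(map)
  mx <- floor(n1 / 2); my <- floor(n2 / 2)
  ac <- matrix(NA_real_, 2 * mx + 1, 2 * my + 1)
  for (dx in -mx:mx) for (dy in -my:my) {
    i1 <- max(1, 1 + dx):min(n1, n1 + dx)
    j1 <- max(1, 1 + dy):min(n2, n2 + dy)
    a <- map[i1, j1]; b <- map[i1 - dx, j1 - dy]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) > 20 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
      ac[dx + mx + 1, dy + my + 1] <- stats::cor(a[ok], b[ok])
    }
  }
  cx <- mx + 1; cy <- my + 1
  rr <- sqrt(outer((seq_len(nrow(ac)) - cx)^2, (seq_len(ncol(ac)) - cy)^2, "+"))
  rmax <- min(mx, my)
  ann <- rr > rmax * 0.25 & rr <= rmax
  rotate_cor <- function(theta) {
    co <- cos(theta); si <- sin(theta)
    v1 <- c(); v2 <- c()
    for (i in seq_len(nrow(ac))) for (j in seq_len(ncol(ac))) {
      if (!ann[i, j] || is.na(ac[i, j])) next
      x <- i - cx; y <- j - cy
      ir <- round(cx + co * x - si * y); jr <- round(cy + si * x + co * y)
      if (ir < 1 || ir > nrow(ac) || jr < 1 || jr > ncol(ac)) next
      if (is.na(ac[ir, jr])) next
      v1 <- c(v1, ac[i, j]); v2 <- c(v2, ac[ir, jr])
    }
    stats::cor(v1, v2)
  }
  r60 <- rotate_cor(pi / 3); r120 <- rotate_cor(2 * pi / 3)
  r30 <- rotate_cor(pi / 6); r90 <- rotate_cor(pi / 2); r150 <- rotate_cor(5 * pi / 6)
  min(r60, r120) - max(r30, r90, r150)
}
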