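#' Behavioral trajectories
#'
#' A trajectory is the behavioral input stream that drives the attractor
#' networks: uniformly sampled time, 2D position (metres), head direction
#' (radians, wrapped to `(-pi, pi]`), linear speed (m/s, nonnegative) and
#' signed angular head speed (rad/s). Positions advance by `v * dt` along the
#' current heading each step, so the recorded `v` and `omega` equal the finite
#' differences of `z` and `theta_hd` to floating precision.
#'
#' Under the standard mathematical convention used throughout (angles
#' counterclockwise-positive), a clockwise head turn has negative `omega`.
#'
#' @name trajectory
#' @aliases Trajectory
NULL

new_trajectory <- function(t, x, y, theta_hd, v, omega, dt) {
  stopifnot(length(t) == length(x), length(x) == length(y),
            length(y) == length(theta_hd), length(theta_hd) == length(v),
            length(v) == length(omega), all(v >= 0))
  out <- data.frame(t = t, x = x, y = y,
                    theta_hd = wrap_angle(theta_hd), v = v, omega = omega)
  attr(out, "dt") <- dt
  class(out) <- c("trajectory", "data.frame")
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples, dt = %g s, duration = %.3f s\n",
              nrow(x), attr(x, "dt"), x$t[nrow(x)] - x$t[1]))
  cat(sprintf("  speed range [%.3f, %.3f] m/s, |omega| max %.3f rad/s\n",
              min(x$v), max(x$v), max(abs(x$omega))))
  invisible(x)
}

#' Straight run at constant speed and fixed head direction
#'
#' @param speed Linear running speed in m/s (>= 0).
#' @param heading Fixed head direction in radians.
#' @param duration Run duration in seconds (> 0).
#' @param dt Time step in seconds (default 1 ms).
#' @param start Starting position, metres.
#' @return A [trajectory] with `duration/dt + 1` samples; the final
#'   displacement is exactly `speed * duration`.
#' @export
#' @examples
#' tr <- make_straight_run(0.5, pi / 4, 1)
#' sqrt(tr$x[nrow(tr)]^2 + tr$y[nrow(tr)]^2)  # 0.5 m
make_straight_run <- function(speed, heading, duration, dt = 1e-3,
                              start = c(0, 0)) {
  stopifnot(speed >= 0, duration > 0, dt > 0)
  t <- seq(0, duration, by = dt)
  new_trajectory(t,
                 x = start[1] + speed * t * cos(heading),
                 y = start[2] + speed * t * sin(heading),
                 theta_hd = rep(wrap_angle(heading), length(t)),
                 v = rep(speed, length(t)),
                 omega = rep(0, length(t)),
                 dt = dt)
}

#' Constant-rate head rotation, optionally while moving
#'
#' The heading advances by `angular_speed * dt` per step; the position advances
#' by `linear_speed * dt` along the instantaneous heading (a circular arc when
#' both are nonzero). Clockwise rotation corresponds to negative
#' `angular_speed`.
#'
#' @param angular_speed Signed angular head speed, rad/s.
#' @param initial_heading Heading at t = 0, radians.
#' @param duration Seconds (> 0).
#' @param dt Time step, seconds.
#' @param linear_speed Linear speed in m/s (default 0: rotation on the spot).
#' @param start Starting position, metres.
#' @return A [trajectory].
#' @export
make_rotation <- function(angular_speed, initial_heading, duration, dt = 1e-3,
                          linear_speed = 0, start = c(0, 0)) {
  stopifnot(duration > 0, dt > 0, linear_speed >= 0)
  t <- seq(0, duration, by = dt)
  n <- length(t)
  theta <- initial_heading + angular_speed * t
  x <- c(start[1], start[1] + cumsum(linear_speed * dt * cos(theta[-n])))
  y <- c(start[2], start[2] + cumsum(linear_speed * dt * sin(theta[-n])))
  new_trajectory(t, x, y, theta,
                 v = rep(linear_speed, n),
                 omega = rep(angular_speed, n),
                 dt = dt)
}

#' Multi-segment trajectory (straight runs, turns, immobility)
#'
#' Segments are chained continuously: each segment starts at the final
#' position and heading of the previous one, so `z` and `theta_hd` are
#' continuous at the joins and turns are constant-omega arcs rather than
#' instantaneous heading jumps. A segment is a list with a `kind` field:
#' \describe{
#'   \item{`straight`}{fields `speed`, `duration`, optional `heading` (only
#'     honoured for the first segment; a mismatching explicit heading later in
#'     the chain is a chaining error).}
#'   \item{`turn`}{fields `angular_speed`, `duration`, optional `speed`
#'     (linear speed during the turn, default 0).}
#'   \item{`still`}{field `duration`.}
#' }
#'
#' @param segments Nonempty list of segment specifications.
#' @param dt Time step, seconds.
#' @param start Starting position, metres.
#' @param heading Initial heading, radians (used unless the first segment
#'   specifies one).
#' @return A [trajectory].
#' @export
#' @examples
#' tr <- make_segments(list(
#'   list(kind = "straight", speed = 0.4, duration = 1),
#'   list(kind = "turn", angular_speed = pi / 2, duration = 1, speed = 0.4),
#'   list(kind = "straight", speed = 0.4, duration = 1)
#' ), dt = 1e-3)
make_segments <- function(segments, dt = 1e-3, start = c(0, 0), heading = 0) {
  stopifnot(is.list(segments), length(segments) >= 1, dt > 0)
  pos <- start
  head_cur <- heading
  pieces <- vector("list", length(segments))
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    if (is.null(seg$kind)) stop("each segment needs a 'kind' field")
    if (!is.null(seg$heading)) {
      if (k == 1L) {
        head_cur <- seg$heading
      } else if (abs(wrap_angle(seg$heading - head_cur)) > 1e-9) {
        stop("discontinuous chaining: segment ", k, " requests heading ",
             signif(seg$heading, 4), " but the chain arrives at ",
             signif(head_cur, 4))
      }
    }
    piece <- switch(seg$kind,
      straight = make_straight_run(seg$speed, head_cur, seg$duration, dt,
                                   start = pos),
      still = make_straight_run(0, head_cur, seg$duration, dt, start = pos),
      turn = make_rotation(seg$angular_speed, head_cur, seg$duration, dt,
                           linear_speed = if (is.null(seg$speed)) 0 else seg$speed,
                           start = pos),
      stop("unknown segment kind: ", seg$kind)
    )
    n <- nrow(piece)
    pos <- c(piece$x[n], piece$y[n])
    head_cur <- piece$theta_hd[n]
    pieces[[k]] <- piece
  }
  # drop the duplicated joint sample at the start of every later piece
  for (k in seq_along(pieces)[-1]) pieces[[k]] <- pieces[[k]][-1, ]
  out <- do.call(rbind, pieces)
  out$t <- seq(0, by = dt, length.out = nrow(out))
  n <- nrow(out)
  # enforce the finite-difference invariant across segment joins
  out$v <- c(sqrt(diff(out$x)^2 + diff(out$y)^2) / dt, out$v[n])
  out$omega <- c(wrap_angle(diff(out$theta_hd)) / dt, out$omega[n])
  attr(out, "dt") <- dt
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Random walk in a square arena
#'
#' Smooth (AR(1)) speed and turning processes with reflective turning at the
#' arena walls: when the next step would exit the arena, the heading is rotated
#' toward the arena center. The walk is a pure function of its arguments and
#' seed; the caller's RNG state is left untouched.
#'
#' @param duration Seconds.
#' @param dt Time step, seconds.
#' @param speed_stats List with `mean` and `sd` of the target speed (m/s).
#' @param turn_stats List with `sd`, the standard deviation of the angular
#'   speed process (rad/s).
#' @param arena_size Side length of the square arena, metres (> 0).
#' @param seed Integer seed (required, for reproducibility).
#' @return A [trajectory] with all positions inside `[0, arena_size]^2`.
#' @export
make_random_walk <- function(duration, dt = 1e-3,
                             speed_stats = list(mean = 0.25, sd = 0.08),
                             turn_stats = list(sd = 2.5),
                             arena_size = 1.5, seed) {
  stopifnot(duration > 0, dt > 0, arena_size > 0)
  if (missing(seed)) stop("a seed is required for reproducibility")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  t <- seq(0, duration, by = dt)
  n <- length(t)
  # AR(1) with ~0.5 s correlation time for both speed and angular speed
  rho <- exp(-dt / 0.5)
  innov_sd <- sqrt(1 - rho^2)
  sp <- numeric(n); om <- numeric(n)
  sp[1] <- speed_stats$mean
  for (i in 2:n) {
    sp[i] <- speed_stats$mean + rho * (sp[i - 1] - speed_stats$mean) +
      innov_sd * speed_stats$sd * stats::rnorm(1)
    om[i] <- rho * om[i - 1] + innov_sd * turn_stats$sd * stats::rnorm(1)
  }
  sp <- pmax(sp, 0)
  x <- numeric(n); y <- numeric(n); theta <- numeric(n)
  x[1] <- arena_size / 2; y[1] <- arena_size / 2
  theta[1] <- stats::runif(1, -pi, pi)
  ctr <- c(arena_size / 2, arena_size / 2)
  for (i in 2:n) {
    th_prop <- theta[i - 1] + om[i] * dt
    step <- sp[i - 1] * dt
    xn <- x[i - 1] + step * cos(th_prop)
    yn <- y[i - 1] + step * sin(th_prop)
    if (xn < 0 || xn > arena_size || yn < 0 || yn > arena_size) {
      # reflective turning: rotate heading toward the arena center
      to_ctr <- atan2(ctr[2] - y[i - 1], ctr[1] - x[i - 1])
      turn <- wrap_angle(to_ctr - theta[i - 1])
      th_prop <- theta[i - 1] + sign(turn) * min(abs(turn), pi / 2)
      om[i] <- wrap_angle(th_prop - theta[i - 1]) / dt
      xn <- min(max(x[i - 1] + step * cos(th_prop), 0), arena_size)
      yn <- min(max(y[i - 1] + step * sin(th_prop), 0), arena_size)
    }
    x[i] <- xn; y[i] <- yn; theta[i] <- th_prop
  }
  v <- c(sqrt(diff(x)^2 + diff(y)^2) / dt, sp[n - 1])  # wall clamps shorten steps
  omega <- c(diff(theta) / dt, om[n])
  new_trajectory(t, x, y, theta, v = v, omega = omega, dt = dt)
}

#' Read/write trajectories as CSV
#'
#' Plain CSV with columns `t,x,y,theta_hd,v,omega` (SI units, radians).
#'
#' @param traj A [trajectory].
#' @param file Path to a CSV file.
#' @return `write_trajectory` returns `file` invisibly; `read_trajectory`
#'   returns a [trajectory].
#' @export
write_trajectory <- function(traj, file) {
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  d <- utils::read.csv(file)
  need <- c("t", "x", "y", "theta_hd", "v", "omega")
  if (!all(need %in% names(d))) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ","))
  }
  dt <- stats::median(diff(d$t))
  new_trajectory(d$t, d$x, d$y, d$theta_hd, d$v, d$omega, dt = dt)
}

#' Extract a time window of a trajectory
#'
#' Subsets a trajectory to `from <= t <= to`, preserving the sampling step.
#' Useful for discarding warm-in transients before computing statistics.
#'
#' @param traj A [trajectory].
#' @param from,to Window bounds in seconds (defaults: full range).
#' @return A [trajectory].
#' @export
trajectory_window <- function(traj, from = -Inf, to = Inf) {
  dt <- attr(traj, "dt")
  out <- traj[traj$t >= from & traj$t <= to, ]
  attr(out, "dt") <- dt
  class(out) <- c("trajectory", "data.frame")
  out
}
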