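#' Parameters of the head-direction ring attractor
#'
#' Theta-modulated head-direction (HD) cells are modeled as a continuous ring
#' attractor with divisive global inhibition, firing rate adaptation and a
#' speed-scaled sinusoidal theta modulation of the directional sensory input.
#'
#' Discrete sums over cells carry the lattice measure `2*pi/N`, so the
#' dynamics are invariant to the number of cells (checked by the
#' resolution-doubling tests); `J0`, `k` and `A` are therefore in continuum
#' units. The connectivity width `b` (0.4 rad) and the time constants (10 ms
#' rate, 100 ms adaptation) follow the published model description; the
#' remaining strengths are calibrated defaults (see the methods vignette) and
#' all overridable.
#'
#' @param N Number of HD cells (>= 8).
#' @param tau Rate time constant, seconds.
#' @param b Gaussian width of recurrent connections and sensory input, radians.
#' @param J0 Recurrent connection strength.
#' @param k Divisive global-inhibition strength.
#' @param A Baseline sensory input strength.
#' @param b_in Gaussian width of the head-direction sensory input, radians.
#'   The printed model ties the recurrent width `b` to the connectivity; the
#'   input tuning width is a separate calibrated constant (a broad, shallow
#'   input basin lets theta troughs release the bump into sweeps while keeping
#'   it anchored at large offsets).
#' @param abar Theta-modulation speed scaling (s/m): the theta gain is
#'   `1 + abar * v * sin(omega_theta * t)`.
#' @param m Firing rate adaptation strength (0 disables adaptation).
#' @param tau_a Adaptation time constant, seconds (must exceed `tau`).
#' @param omega_theta Theta angular frequency, rad/s (default 9 Hz).
#' @param conn_noise SD of multiplicative i.i.d. jitter applied to the
#'   recurrent kernel weights (0 = homogeneous connections).
#' @param conn_seed Seed for the connection jitter.
#' @return An object of class `hd_params`.
#' @export
hd_params <- function(N = 100, tau = 0.010, b = 0.4,
                      J0 = 1, k = 0.05, A = 4, b_in = 0.4,
                      abar = 1.3, m = 0.49,
                      tau_a = 0.100, omega_theta = 2 * pi * 9,
                      conn_noise = 0, conn_seed = 1L) {
  stopifnot(N >= 8, tau > 0, tau_a > tau, b > 0, b_in > 0, k >= 0,
            conn_noise >= 0)
  structure(list(N = as.integer(N), tau = tau, b = b, J0 = J0, k = k, A = A,
                 b_in = b_in, abar = abar, m = m, tau_a = tau_a,
                 omega_theta = omega_theta,
                 conn_noise = conn_noise, conn_seed = as.integer(conn_seed)),
            class = "hd_params")
}

#' Gaussian recurrent kernel on the ring
#'
#' `J[i, j] = J0 / (2 pi b^2) * exp(-d(x_i, x_j)^2 / (4 b^2))` with `d` the
#' circular distance; translation-invariant on the uniform ring (every row is
#' a rotation of the first). Optional multiplicative jitter models
#' inhomogeneous connections for the sensitivity analysis.
#'
#' @param params An [hd_params] object.
#' @return An `N x N` symmetric matrix (exactly symmetric only when
#'   `conn_noise = 0`).
#' @export
build_ring_kernel <- function(params) {
  x <- hd_pref_dirs(params$N)
  d <- ring_distance(outer(x, x, "-"), 0)
  J <- params$J0 / (2 * pi * params$b^2) * exp(-d^2 / (4 * params$b^2))
  if (params$conn_noise > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(params$conn_seed)
    J <- J * (1 + params$conn_noise * stats::rnorm(length(J)))
  }
  J
}

#' Preferred directions of N cells equally spaced on the ring
#' @param N Number of cells.
#' @return Angles in `(-pi, pi]`.
#' @export
hd_pref_dirs <- function(N) wrap_angle(2 * pi * (seq_len(N) - 1) / N)

#' Speed-scaled theta gain
#'
#' The medial-septal theta modulation `1 + abar * v * sin(omega_theta * t)`:
#' its oscillation magnitude scales linearly with running speed, so it
#' vanishes at rest and when `abar = 0` (septal inactivation).
#'
#' @param v Running speed, m/s (>= 0).
#' @param t Time, seconds.
#' @param abar Speed scaling factor, s/m.
#' @param omega_theta Theta angular frequency, rad/s.
#' @return Dimensionless gain.
#' @export
theta_gain <- function(v, t, abar, omega_theta) {
  stopifnot(all(v >= 0))
  1 + abar * v * sin(omega_theta * t)
}

#' Head-direction-dependent sensory input
#'
#' Gaussian input peaked at the cell whose preferred direction is closest to
#' the current head direction, multiplied by the theta gain.
#'
#' @param theta_hd Head direction, radians.
#' @param v Running speed, m/s.
#' @param t Time, seconds.
#' @param params An [hd_params] object.
#' @return Input vector of length `N`.
#' @export
hd_input <- function(theta_hd, v, t, params) {
  x <- hd_pref_dirs(params$N)
  a <- theta_gain(v, t, params$abar, params$omega_theta)
  params$A * a * exp(-ring_distance(x, theta_hd)^2 / (4 * params$b_in^2))
}

#' Divisive (global-inhibition) firing rates
#'
#' `r_j = h_j^2 / (1 + k * measure * sum(h^2))`. The `measure` argument is the
#' lattice cell size used by the networks to keep the inhibition term
#' resolution-invariant; the default 1 gives the literal per-cell sum.
#'
#' @param h Synaptic input vector (or matrix field).
#' @param k Global inhibition strength (>= 0).
#' @param measure Lattice measure multiplying the sum (default 1).
#' @return Nonnegative rates, same shape as `h`.
#' @export
#' @examples
#' divisive_rates(c(2, 0, 0), k = 1)  # 4 / (1 + 4) in the first entry
divisive_rates <- function(h, k, measure = 1) {
  stopifnot(k >= 0)
  h^2 / (1 + k * measure * sum(h^2))
}

#' Assemble a ready-to-step HD network
#'
#' Precomputes the preferred directions and the recurrent kernel scaled by the
#' ring lattice measure.
#'
#' @param params An [hd_params] object.
#' @return An object of class `hd_network`.
#' @export
hd_network <- function(params) {
  measure <- 2 * pi / params$N
  structure(list(params = params,
                 x = hd_pref_dirs(params$N),
                 Jm = build_ring_kernel(params) * measure,
                 measure = measure),
            class = "hd_network")
}

#' @export
print.hd_network <- function(x, ...) {
  p <- x$params
  cat(sprintf("<hd_network> N=%d b=%.2f rad J0=%.3g k=%.3g A=%.3g m=%.3g abar=%.3g theta=%.1f Hz\n",
              p$N, p$b, p$J0, p$k, p$A, p$m, p$abar, p$omega_theta / (2 * pi)))
  invisible(x)
}

hd_state_init <- function(net, theta_hd) {
  h <- hd_input(theta_hd, 0, 0, net$params)
  list(h = h, a = rep(0, net$params$N),
       r = divisive_rates(h, net$params$k, net$measure))
}

check_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop("numerical divergence: non-finite values in '", name, "'",
         call. = FALSE)
  }
  x
}

#' One explicit-Euler step of the HD ring attractor
#'
#' Updates the synaptic input `h` (leak, recurrent drive, adaptation, external
#' input) and the adaptation variable `a` (slow low-pass of `m * r`), then
#' recomputes the rates from the updated `h`.
#'
#' @param net An [hd_network].
#' @param state List with vectors `h`, `a`, `r`.
#' @param input External input vector (from [hd_input]).
#' @param dt Time step, seconds; must satisfy `dt <= tau / 5`.
#' @return The updated state.
#' @export
step_hd <- function(net, state, input, dt) {
  p <- net$params
  stopifnot(dt <= p$tau / 5)
  rec <- drop(net$Jm %*% state$r)
  h <- state$h + dt / p$tau * (-state$h + rec - state$a + input)
  a <- state$a + dt / p$tau_a * (-state$a + p$m * state$r)
  check_finite(h, "h"); check_finite(a, "a")
  list(h = h, a = a, r = divisive_rates(h, p$k, net$measure))
}

#' Internal direction from HD population rates
#'
#' Circular population-vector mean: the argument of
#' `sum(r_j * exp(1i * x_j))`. Errors when there is no coherent bump (the
#' mean resultant length falls below `tol`).
#'
#' @param r Nonnegative rate vector.
#' @param x Preferred directions (defaults to `N` equally spaced angles).
#' @param tol Coherence threshold on the mean resultant length.
#' @return The bump center, radians in `(-pi, pi]`.
#' @export
internal_direction <- function(r, x = hd_pref_dirs(length(r)), tol = 0.1) {
  out <- internal_direction_or_na(r, x, tol)
  if (is.na(out)) {
    stop("undefined internal direction: no coherent bump (resultant below ",
         tol, ")", call. = FALSE)
  }
  out
}

internal_direction_or_na <- function(r, x, tol = 0.1) {
  s <- sum(r)
  if (s <= 0) return(NA_real_)
  z <- sum(r * exp(1i * x))
  if (Mod(z) / s < tol) return(NA_real_)
  Arg(z)
}

#' Simulate the HD ring attractor along a trajectory
#'
#' The network is initialized by a warmup on the first trajectory sample with
#' the theta gain frozen at 1 (and adaptation enabled), then driven by the
#' full trajectory. Deterministic given its inputs.
#'
#' @param traj A [trajectory].
#' @param params An [hd_params] object.
#' @param warmup Warmup duration, seconds (>= 0).
#' @return An object of class `hd_run`: time, the `T x N` rate matrix, the
#'   internal-direction trace (`NA` where the bump is incoherent), the
#'   population rate, theta phase, and the inputs used.
#' @export
run_hd <- function(traj, params = hd_params(), warmup = 0.5) {
  stopifnot(inherits(traj, "trajectory"), warmup >= 0)
  dt <- attr(traj, "dt")
  net <- hd_network(params)
  state <- hd_state_init(net, traj$theta_hd[1])
  n_warm <- round(warmup / dt)
  if (n_warm > 0) {
    # theta gain frozen at 1; the final 30 ms seed the bump a small, fixed
    # angle off the head direction so the sweep instability does not have to
    # grow out of floating-point noise (deterministic symmetry breaking)
    i0 <- hd_input(traj$theta_hd[1], 0, 0, params)
    ik <- hd_input(traj$theta_hd[1] + 0.05, 0, 0, params)
    n_kick <- min(n_warm, round(0.03 / dt))
    for (i in seq_len(n_warm - n_kick)) state <- step_hd(net, state, i0, dt)
    for (i in seq_len(n_kick)) state <- step_hd(net, state, ik, dt)
  }
  n <- nrow(traj)
  R <- matrix(0, n, params$N)
  for (i in seq_len(n)) {
    inp <- hd_input(traj$theta_hd[i], traj$v[i], traj$t[i], params)
    state <- step_hd(net, state, inp, dt)
    R[i, ] <- state$r
  }
  center <- apply(R, 1, internal_direction_or_na, x = net$x)
  structure(list(t = traj$t, r = R, center = center,
                 pop_rate = rowSums(R) * net$measure,
                 x = net$x,
                 theta_phase = (params$omega_theta * traj$t) %% (2 * pi),
                 params = params, traj = traj, warmup = warmup),
            class = "hd_run")
}

#' @export
print.hd_run <- function(x, ...) {
  cat(sprintf("<hd_run> %d steps, N=%d, %.1f%% coherent, peak rate %.3g\n",
              length(x$t), ncol(x$r), 100 * mean(!is.na(x$center)),
              max(x$r)))
  invisible(x)
}
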