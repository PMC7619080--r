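#' Parameters of a grid-cell torus attractor module
#'
#' Grid cells of one module are modeled as a continuous attractor on a
#' `n_side x n_side` sheet of preferred phases with periodic boundaries (a
#' torus). The module receives a feedforward phase input from conjunctive
#' grid-by-direction cells: a weighted sum of Gaussian bumps centered at the
#' animal's position phase, each shifted by `w0` (phase radians) along the
#' preferred direction of the contributing HD cells, gain-modulated by running
#' speed (`T0 * v + A`) and by the septal theta gain.
#'
#' As for the ring, sums carry the lattice measure `(2*pi/n_side)^2`, making
#' the dynamics resolution-invariant; headline simulations use
#' `n_side = 100`, tests use 32-48. Printed model constants: `b = 0.8` (about
#' 13% of the sheet width), `w0 = 1/9` phase radians (about 1.8% of the sheet
#' width), adaptation strength 0.7 (dorsal) to 1.8 (ventral). The remaining
#' strengths are calibrated defaults.
#'
#' @param n_side Cells per torus dimension (>= 16).
#' @param tau Rate time constant, seconds.
#' @param b Gaussian kernel width, phase radians.
#' @param J0 Recurrent strength.
#' @param k Divisive global-inhibition strength.
#' @param lambda Grid spacing, metres.
#' @param w0 Conjunctive-cell phase offset magnitude, phase radians.
#' @param T0 Speed gain of the conjunctive input (per m/s).
#' @param A Baseline conjunctive input strength.
#' @param abar Theta-modulation speed scaling (s/m).
#' @param m Firing rate adaptation strength.
#' @param tau_a Adaptation time constant, seconds.
#' @param omega_theta Theta angular frequency, rad/s (shared with the HD
#'   ring; default 9 Hz).
#' @param conn_noise SD of multiplicative jitter on the recurrent kernel.
#' @param conn_seed Seed for the connection jitter.
#' @return An object of class `grid_params`.
#' @export
grid_params <- function(n_side = 48, tau = 0.010, b = 0.8,
                        J0 = 1, k = 0.05, lambda = 0.4,
                        w0 = 1 / 9, T0 = 4.57, A = 1,
                        abar = 1.3, m = 0.7,
                        tau_a = 0.100, omega_theta = 2 * pi * 9,
                        conn_noise = 0, conn_seed = 1L) {
  stopifnot(n_side >= 16, lambda > 0, m >= 0, tau_a > tau, conn_noise >= 0)
  structure(list(n_side = as.integer(n_side), tau = tau, b = b, J0 = J0,
                 k = k, lambda = lambda, w0 = w0, T0 = T0, A = A,
                 abar = abar, m = m, tau_a = tau_a, omega_theta = omega_theta,
                 conn_noise = conn_noise, conn_seed = as.integer(conn_seed)),
            class = "grid_params")
}

#' Hexagonal phase mapping from physical space to the torus
#'
#' Projects position onto two axes sixty degrees apart with
#' `W = rbind(c(1, -1/sqrt(3)), c(0, 2/sqrt(3)))`, wraps modulo the grid
#' spacing `lambda`, and scales to phase radians:
#' `phi = 2 * pi * (W z mod lambda) / lambda`. The map is invariant under the
#' hexagonal lattice translations `z + lambda * (1, 0)` and
#' `z + lambda * (1/2, sqrt(3)/2)`.
#'
#' @param z Position in metres: a length-2 vector or an `n x 2` matrix.
#' @param lambda Grid spacing, metres.
#' @return Phase coordinates in `[0, 2*pi)`, same shape as `z`.
#' @export
phase_map <- function(z, lambda) {
  stopifnot(all(is.finite(z)), lambda > 0)
  W <- w_trans()
  if (is.matrix(z)) {
    u <- z %*% t(W)
  } else {
    u <- matrix(drop(W %*% z), 1)
  }
  phi <- 2 * pi * (u %% lambda) / lambda
  if (is.matrix(z)) phi else drop(phi)
}

w_trans <- function() rbind(c(1, -1 / sqrt(3)), c(0, 2 / sqrt(3)))
w_trans_inv <- function() rbind(c(1, 1 / 2), c(0, sqrt(3) / 2))

#' Circular distance on the torus
#'
#' Euclidean norm of the componentwise circular differences (each wrapped to
#' `(-pi, pi]`).
#'
#' @param phi_a,phi_b Phase coordinates: length-2 vectors or `n x 2` matrices.
#' @return Nonnegative distances in phase units.
#' @export
torus_distance <- function(phi_a, phi_b) {
  da <- wrap_angle(phi_a - phi_b)
  if (is.matrix(da)) sqrt(rowSums(da^2)) else sqrt(sum(da^2))
}

#' Gaussian recurrent kernel on the torus
#'
#' `J(d) = J0 / (2 pi b^2) * exp(-d^2 / (4 b^2))` evaluated on the phase
#' lattice with the origin at index `[1, 1]`, for use as a circular
#' convolution kernel (the full `N_g x N_g` weight matrix is never
#' materialized).
#'
#' @param params A [grid_params] object.
#' @return An `n_side x n_side` kernel matrix.
#' @export
build_torus_kernel <- function(params) {
  n <- params$n_side
  phi <- 2 * pi * (seq_len(n) - 1) / n
  dx <- wrap_angle(phi)
  d2 <- outer(dx^2, dx^2, "+")
  K <- params$J0 / (2 * pi * params$b^2) * exp(-d2 / (4 * params$b^2))
  if (params$conn_noise > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(params$conn_seed)
    K <- K * (1 + params$conn_noise * stats::rnorm(length(K)))
  }
  K
}

#' Circular convolution of a field with a torus kernel
#'
#' FFT-based circular convolution; with the kernel from
#' [build_torus_kernel] this equals the dense matrix-vector product of the
#' translation-invariant weight matrix with the vectorized field.
#'
#' @param field An `n x n` matrix.
#' @param kernel_fft The 2D FFT of the kernel (`stats::fft(kernel)`).
#' @return The convolved `n x n` field.
#' @export
torus_convolve <- function(field, kernel_fft) {
  n2 <- length(field)
  Re(stats::fft(stats::fft(field) * kernel_fft, inverse = TRUE)) / n2
}

#' Speed gain of the conjunctive-cell input
#'
#' `T(v) = T0 * v + A`: the firing of conjunctive grid-by-direction cells
#' increases linearly with running speed, so faster running drives the grid
#' bump further.
#'
#' @param v Running speed, m/s (>= 0).
#' @param params A [grid_params] object.
#' @return The input gain.
#' @export
speed_gain <- function(v, params) {
  stopifnot(all(v >= 0))
  params$T0 * v + params$A
}

#' Assemble a ready-to-step grid module
#'
#' @param params A [grid_params] object.
#' @return An object of class `grid_network` with the phase lattice and the
#'   FFT of the measure-scaled recurrent kernel precomputed.
#' @export
grid_network <- function(params) {
  n <- params$n_side
  measure <- (2 * pi / n)^2
  K <- build_torus_kernel(params)
  structure(list(params = params,
                 phi = 2 * pi * (seq_len(n) - 1) / n,
                 kernel = K,
                 kernel_fft = stats::fft(K * measure),
                 measure = measure),
            class = "grid_network")
}

#' @export
print.grid_network <- function(x, ...) {
  p <- x$params
  cat(sprintf("<grid_network> %dx%d lambda=%.3g m b=%.2f m_adapt=%.2f w0=%.3g\n",
              p$n_side, p$n_side, p$lambda, p$b, p$m, p$w0))
  invisible(x)
}

#' Feedforward phase input from conjunctive grid-by-direction cells
#'
#' The closed-form drive implementing the conjunctive layer: a weighted sum,
#' over HD cells `j` with rate `r_h[j]` and preferred direction `x_h[j]`, of
#' Gaussian bumps centered at `psi(z) + w0 * (cos x_j, sin x_j)` on the torus,
#' scaled by the speed gain `T(v)` and the grid theta gain. The Gaussian is
#' separable in the two wrapped phase coordinates, which is exploited for
#' speed.
#'
#' @param r_h HD rate vector.
#' @param x_h HD preferred directions (same length).
#' @param z Animal position, metres (length 2).
#' @param v Running speed, m/s.
#' @param t Time, seconds.
#' @param net A [grid_network].
#' @return The `n x n` input field.
#' @export
conj_input <- function(r_h, x_h, z, v, t, net) {
  p <- net$params
  if (all(r_h == 0)) {
    if (!isTRUE(net$warned_zero)) warning("conjunctive input: all HD rates are zero")
    return(matrix(0, p$n_side, p$n_side))
  }
  psi <- phase_map(z, p$lambda)
  cx <- psi[1] + p$w0 * cos(x_h)
  cy <- psi[2] + p$w0 * sin(x_h)
  gx <- exp(-wrap_angle(outer(net$phi, cx, "-"))^2 / (4 * p$b^2))
  gy <- exp(-wrap_angle(outer(net$phi, cy, "-"))^2 / (4 * p$b^2))
  a_g <- theta_gain(v, t, p$abar, p$omega_theta)
  measure_h <- 2 * pi / length(r_h)
  scale <- a_g * speed_gain(v, p) * measure_h
  scale * ((gx * rep(r_h, each = p$n_side)) %*% t(gy))
}

grid_state_init <- function(net, z) {
  p <- net$params
  psi <- phase_map(z, p$lambda)
  gx <- exp(-wrap_angle(net$phi - psi[1])^2 / (4 * p$b^2))
  gy <- exp(-wrap_angle(net$phi - psi[2])^2 / (4 * p$b^2))
  g <- p$A * outer(gx, gy)
  list(g = g, a = matrix(0, p$n_side, p$n_side),
       r = divisive_rates(g, p$k, net$measure))
}

#' One explicit-Euler step of a grid module
#'
#' As [step_hd], with the recurrent drive computed by FFT circular
#' convolution on the torus.
#'
#' @param net A [grid_network].
#' @param state List with `n x n` matrices `g`, `a`, `r`.
#' @param input External input field (from [conj_input]).
#' @param dt Time step, seconds; must satisfy `dt <= tau / 5`.
#' @return The updated state.
#' @export
step_grid <- function(net, state, input, dt) {
  p <- net$params
  stopifnot(dt <= p$tau / 5)
  rec <- torus_convolve(state$r, net$kernel_fft)
  g <- state$g + dt / p$tau * (-state$g + rec - state$a + input)
  a <- state$a + dt / p$tau_a * (-state$a + p$m * state$r)
  check_finite(g, "g"); check_finite(a, "a")
  list(g = g, a = a, r = divisive_rates(g, p$k, net$measure))
}

#' Simulate the coupled HD-ring and grid-torus model
#'
#' One HD ring simulation drives one or several independent grid modules
#' (differing in grid spacing and adaptation strength) through the
#' conjunctive-cell phase input. Both networks are initialized by a warmup on
#' the first trajectory sample with the theta gain frozen at 1, then driven by
#' the full trajectory. All modules share the trajectory time step and theta
#' frequency.
#'
#' @param traj A [trajectory].
#' @param hd An [hd_params] object.
#' @param grid A [grid_params] object or a list of them (one per module).
#' @param warmup Warmup duration, seconds.
#' @param probe_cells Optional integer vector of grid-cell lattice indices
#'   (into the `n x n` field) whose rates are recorded per module.
#' @param record_hd_rates If `TRUE` (default) keep the full `T x N` HD rate
#'   matrix.
#' @return An object of class `coupled_run` with elements `t`, `theta_phase`,
#'   `hd` (rates, internal-direction trace, population rate), and `modules`,
#'   a list with per-module phase bump-center traces (`T x 2`, `NA` rows where
#'   the bump is incoherent), population rate and probed-cell rates.
#' @export
run_coupled <- function(traj, hd = hd_params(), grid = grid_params(),
                        warmup = 0.5, probe_cells = NULL,
                        record_hd_rates = TRUE) {
  stopifnot(inherits(traj, "trajectory"), warmup >= 0)
  if (inherits(grid, "grid_params")) grid <- list(grid)
  dt <- attr(traj, "dt")
  for (gp in grid) {
    if (abs(gp$omega_theta - hd$omega_theta) > 1e-12) {
      stop("all modules must share omega_theta with the HD ring")
    }
  }
  hnet <- hd_network(hd)
  hstate <- hd_state_init(hnet, traj$theta_hd[1])
  gnets <- lapply(grid, grid_network)
  gstates <- lapply(gnets, grid_state_init, z = c(traj$x[1], traj$y[1]))
  n_warm <- round(warmup / dt)
  z1 <- c(traj$x[1], traj$y[1])
  if (n_warm > 0) {
    # as in run_hd: theta gain frozen at 1, with a small fixed directional
    # kick in the last 30 ms to break the left-right symmetry deterministically
    hi0 <- hd_input(traj$theta_hd[1], 0, 0, hd)
    hik <- hd_input(traj$theta_hd[1] + 0.05, 0, 0, hd)
    n_kick <- min(n_warm, round(0.03 / dt))
    for (i in seq_len(n_warm)) {
      hstate <- step_hd(hnet, hstate,
                        if (i > n_warm - n_kick) hik else hi0, dt)
      for (mdx in seq_along(gnets)) {
        gi0 <- conj_input(hstate$r, hnet$x, z1, 0, 0, gnets[[mdx]])
        gstates[[mdx]] <- step_grid(gnets[[mdx]], gstates[[mdx]], gi0, dt)
      }
    }
  }
  n <- nrow(traj)
  R <- if (record_hd_rates) matrix(0, n, hd$N) else NULL
  hd_center <- numeric(n); hd_pop <- numeric(n)
  mods <- lapply(gnets, function(gn) {
    list(params = gn$params,
         center = matrix(NA_real_, n, 2),
         pop_rate = numeric(n),
         peak_rate = numeric(n),
         probe = if (is.null(probe_cells)) NULL
                 else matrix(0, n, length(probe_cells)),
         probe_cells = probe_cells)
  })
  for (i in seq_len(n)) {
    z <- c(traj$x[i], traj$y[i]); v <- traj$v[i]; ti <- traj$t[i]
    hstate <- step_hd(hnet, hstate, hd_input(traj$theta_hd[i], v, ti, hd), dt)
    if (record_hd_rates) R[i, ] <- hstate$r
    hd_center[i] <- internal_direction_or_na(hstate$r, hnet$x)
    hd_pop[i] <- sum(hstate$r) * hnet$measure
    for (mdx in seq_along(gnets)) {
      gn <- gnets[[mdx]]
      gstates[[mdx]] <- step_grid(gn, gstates[[mdx]],
                                  conj_input(hstate$r, hnet$x, z, v, ti, gn),
                                  dt)
      r <- gstates[[mdx]]$r
      ctr <- bump_center_torus_or_na(r, gn$phi)
      mods[[mdx]]$center[i, ] <- ctr
      mods[[mdx]]$pop_rate[i] <- sum(r) * gn$measure
      mods[[mdx]]$peak_rate[i] <- max(r)
      if (!is.null(probe_cells)) mods[[mdx]]$probe[i, ] <- r[probe_cells]
    }
  }
  structure(list(t = traj$t,
                 theta_phase = (hd$omega_theta * traj$t) %% (2 * pi),
                 hd = list(r = R, center = hd_center, pop_rate = hd_pop,
                           x = hnet$x, params = hd),
                 modules = mods, traj = traj, warmup = warmup),
            class = "coupled_run")
}

#' @export
print.coupled_run <- function(x, ...) {
  cat(sprintf("<coupled_run> %d steps, %d grid module(s), theta %.1f Hz\n",
              length(x$t), length(x$modules),
              x$hd$params$omega_theta / (2 * pi)))
  for (m in x$modules) {
    cat(sprintf("  module: lambda=%.3g m, m_adapt=%.2f, n_side=%d, %.1f%% coherent\n",
                m$params$lambda, m$params$m, m$params$n_side,
                100 * mean(!is.na(m$center[, 1]))))
  }
  invisible(x)
}
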