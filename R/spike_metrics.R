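#' Inhomogeneous Poisson spikes from a rate series
#'
#' Per-bin thinning: each time bin emits a spike with probability
#' `rate * dt` (clipped at 1), placed at the bin time. Reproducible given the
#' seed; the caller's RNG state is untouched.
#'
#' @param rate Nonnegative rate series, Hz.
#' @param t Time stamps of the bins, seconds (same length as `rate`), or a
#'   single `dt` from which times `0, dt, ...` are built.
#' @param seed Integer seed.
#' @return An object of class `spike_train`: a list with sorted `times` and
#'   the bin `index` of each spike.
#' @export
poisson_spikes <- function(rate, t, seed) {
  if (any(rate < 0)) stop("rates must be nonnegative")
  if (length(t) == 1) t <- (seq_along(rate) - 1) * t
  stopifnot(length(t) == length(rate))
  dt <- stats::median(diff(t))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  hit <- stats::runif(length(rate)) < pmin(rate * dt, 1)
  structure(list(times = t[hit], index = which(hit), duration = t[length(t)]),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.1f s (mean %.2f Hz)\n",
              length(x$times), x$duration,
              length(x$times) / max(x$duration, .Machine$double.eps)))
  invisible(x)
}

#' Spike-time autocorrelogram
#'
#' Counts of spike-pair lags over +/- 500 ms in 5 ms bins (201 bins,
#' zero-lag self-pairs excluded), normalized by the peak value between 50 ms
#' and 250 ms and then clipped to at most 1, so all values lie in `[0, 1]`.
#'
#' @param train A `spike_train` or a numeric vector of spike times (s).
#' @param window Half-width of the lag range, seconds.
#' @param binwidth Bin width, seconds.
#' @return An object of class `acg`: list with bin-center `lag` (s) and
#'   normalized `value`.
#' @export
autocorrelogram <- function(train, window = 0.5, binwidth = 0.005) {
  times <- if (inherits(train, "spike_train")) train$times else train
  times <- sort(times)
  if (length(times) < 2) stop("insufficient spikes: need at least 2")
  nb <- 2 * round(window / binwidth) + 1
  centers <- (seq_len(nb) - (nb + 1) / 2) * binwidth
  counts <- numeric(nb)
  lim <- window + binwidth / 2
  n <- length(times)
  j0 <- 1
  for (i in seq_len(n)) {
    while (times[i] - times[j0] > lim) j0 <- j0 + 1
    jj <- j0:n
    lags <- times[jj] - times[i]
    lags <- lags[lags <= lim & jj != i]
    if (length(lags)) {
      b <- round(lags / binwidth) + (nb + 1) / 2
      b <- b[b >= 1 & b <= nb]
      tb <- tabulate(b, nb)
      counts <- counts + tb
    }
  }
  # symmetrize: each ordered pair counted once above (i<j and i>j both hit);
  # the loop above counts lags in [-lim, lim] for every i, so both signs done
  ref <- counts[abs(centers) >= 0.050 - 1e-9 & abs(centers) <= 0.250 + 1e-9]
  pk <- max(ref)
  if (pk <= 0) stop("normalization error: zero peak between 50 and 250 ms")
  structure(list(lag = centers, value = pmin(counts / pk, 1), counts = counts),
            class = "acg")
}

#' @export
print.acg <- function(x, ...) {
  cat(sprintf("<acg> %d bins, lag [%.0f, %.0f] ms\n", length(x$lag),
              1000 * min(x$lag), 1000 * max(x$lag)))
  invisible(x)
}

#' Evaluate the theta-skipping autocorrelogram model
#'
#' A cosine at the theta frequency plus a second interfering oscillation at
#' half that frequency, under an exponential decay envelope, plus a narrow
#' Gaussian at zero lag:
#' `y(x) = [a1 (cos(omega x) + 1) + a2 (cos(0.5 omega x) + 1) + b] *
#'  exp(-|x| / tau1) + c * exp(-x^2 / (2 tau2^2))`.
#'
#' @param x Lags, seconds.
#' @param par Named vector/list with `a1`, `a2`, `b`, `c`, `omega`, `tau1`,
#'   `tau2`.
#' @return Model values.
#' @export
skipping_model <- function(x, par) {
  par <- as.list(par)
  (par$a1 * (cos(par$omega * x) + 1) + par$a2 * (cos(0.5 * par$omega * x) + 1) +
     par$b) * exp(-abs(x) / par$tau1) +
    par$c * exp(-x^2 / (2 * par$tau2^2))
}

skipping_bounds <- function() {
  list(lower = c(a1 = 0, a2 = 0, b = 0, c = -1, omega = 10 * pi,
                 tau1 = 1e-3, tau2 = 1e-4),
       upper = c(a1 = 1, a2 = 1, b = 1, c = 1, omega = 18 * pi,
                 tau1 = 5, tau2 = 0.005))
}

#' Fit the theta-skipping model to an autocorrelogram
#'
#' Bounded least squares (`optim` L-BFGS-B) with a deterministic multi-start
#' grid: 8 theta frequencies spanning the 5-9 Hz search band crossed with two
#' amplitude configurations (theta-dominant and skipping-dominant), each
#' refined from the best fit. `p1` and `p2` are the fitted model values at one
#' and two theta periods (`x = 2*pi/omega` and `4*pi/omega`).
#'
#' @param acg An `acg` object (or list with `lag` and `value`).
#' @return An object of class `skipping_fit`: the fitted parameters, `p1`,
#'   `p2`, the theta-skipping index `TS = (p2 - p1) / max(p1, p2)`, and the
#'   residual sum of squares `fit_rss`.
#' @export
fit_skipping_model <- function(acg) {
  x <- acg$lag; y <- acg$value
  stopifnot(length(x) == length(y), all(is.finite(y)))
  bd <- skipping_bounds()
  rss <- function(p) {
    names(p) <- names(bd$lower)
    sum((skipping_model(x, p) - y)^2)
  }
  omegas <- seq(10 * pi, 18 * pi, length.out = 8)
  amp <- list(c(a1 = 0.5, a2 = 0.05), c(a1 = 0.05, a2 = 0.5))
  c0 <- max(0, y[which.min(abs(x))] - stats::median(y))
  best <- NULL
  for (om in omegas) {
    for (aa in amp) {
      p0 <- c(aa["a1"], aa["a2"], b = 0.1, c = c0, omega = om,
              tau1 = 0.3, tau2 = 0.002)
      fit <- try(stats::optim(p0, rss, method = "L-BFGS-B",
                              lower = bd$lower, upper = bd$upper,
                              control = list(maxit = 500)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (is.null(best)) stop("fit error: all starts of the skipping fit failed")
  # polish from the best start
  fit <- try(stats::optim(best$par, rss, method = "L-BFGS-B",
                          lower = bd$lower, upper = bd$upper,
                          control = list(maxit = 2000, factr = 1e4)),
             silent = TRUE)
  if (!inherits(fit, "try-error") && fit$value <= best$value) best <- fit
  p <- as.list(best$par)
  names(p) <- names(bd$lower)
  p1 <- skipping_model(2 * pi / p$omega, p)
  p2 <- skipping_model(4 * pi / p$omega, p)
  structure(c(p, list(p1 = p1, p2 = p2,
                      TS = theta_skipping_index(p1, p2),
                      fit_rss = best$value)),
            class = "skipping_fit")
}

#' @export
print.skipping_fit <- function(x, ...) {
  cat(sprintf(paste0("<skipping_fit> omega=%.2f rad/s (%.2f Hz) a1=%.3f ",
                     "a2=%.3f b=%.3f c=%.3f tau1=%.3f tau2=%.4f\n",
                     "  p1=%.3f p2=%.3f TS=%.3f (rss %.3g)\n"),
              x$omega, x$omega / (2 * pi), x$a1, x$a2, x$b, x$c, x$tau1,
              x$tau2, x$p1, x$p2, x$TS, x$fit_rss))
  invisible(x)
}

#' Theta-cycle-skipping index
#'
#' `(p2 - p1) / max(p1, p2)` for the fitted autocorrelogram values at one
#' (`p1`) and two (`p2`) theta periods; in `[-1, 1]`, positive when the cell
#' tends to fire on alternate theta cycles. Cells with `TS > 0.1` are
#' conventionally called theta-skipping.
#'
#' @param p1,p2 Nonnegative model values at one and two theta cycles.
#' @return The index in `[-1, 1]`.
#' @export
#' @examples
#' theta_skipping_index(0.4, 0.8)  # 0.5
theta_skipping_index <- function(p1, p2) {
  if (max(p1, p2) <= 0) stop("undefined skipping index: p1 = p2 = 0")
  (p2 - p1) / max(p1, p2)
}

#' Directional tuning curve and tuning width
#'
#' Occupancy-normalized firing rate per head-direction bin, circularly
#' smoothed with a wrapped Gaussian. The tuning width is the full width of
#' the smoothed curve at a fraction `width_level` of its peak, in degrees.
#' The default level 0.2 measures the directional firing range (the base
#' width of the tuning field, the convention for head-direction cells);
#' `width_level = 0.5` gives the FWHM.
#'
#' @param train A `spike_train` (or numeric spike times, s).
#' @param traj The [trajectory] the spikes were generated on.
#' @param n_bins Number of direction bins (default 60, i.e. 6 degrees).
#' @param smooth_sd Gaussian smoothing bandwidth, degrees (default 30; a
#'   calibrated estimator constant, see the methods vignette).
#' @param width_level Fraction of the peak at which the width is measured.
#' @return An object of class `tuning_curve`: bin centers (rad), raw and
#'   smoothed rates (Hz), occupancy (s), `width_deg` (NA, with a warning, if
#'   the curve never falls below the level, e.g. uniform firing), and the
#'   preferred direction.
#' @export
tuning_curve <- function(train, traj, n_bins = 60, smooth_sd = 30,
                         width_level = 0.5) {
  times <- if (inherits(train, "spike_train")) train$times else train
  dt <- attr(traj, "dt")
  brk <- seq(-pi, pi, length.out = n_bins + 1)
  centers <- (brk[-1] + brk[-(n_bins + 1)]) / 2
  occ <- as.numeric(table(cut(traj$theta_hd, brk, include.lowest = TRUE))) * dt
  if (any(occ == 0)) {
    warning("empty occupancy bins are masked")
  }
  idx <- pmin(pmax(findInterval(times, traj$t), 1), nrow(traj))
  sd_spk <- traj$theta_hd[idx]
  cnt <- as.numeric(table(cut(sd_spk, brk, include.lowest = TRUE)))
  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  # wrapped Gaussian smoothing
  sd_bins <- smooth_sd / (360 / n_bins)
  lagk <- -n_bins:n_bins
  kern <- exp(-(lagk / sd_bins)^2 / 2)
  kern <- kern / sum(kern)
  r0 <- rate; r0[is.na(r0)] <- 0
  wts <- as.numeric(!is.na(rate))
  smq <- function(v) {
    sapply(seq_len(n_bins), function(i) {
      j <- ((i - 1 + lagk) %% n_bins) + 1
      sum(kern * v[j])
    })
  }
  num <- smq(r0); den <- smq(wts)
  smooth <- ifelse(den > 0, num / den, NA_real_)
  width <- tuning_width_from_curve(centers, smooth, width_level)
  structure(list(dir = centers, rate = rate, smooth = smooth, occupancy = occ,
                 width_deg = width,
                 preferred = centers[which.max(smooth)],
                 width_level = width_level, smooth_sd = smooth_sd),
            class = "tuning_curve")
}

tuning_width_from_curve <- function(dir, curve, level) {
  ok <- !is.na(curve)
  if (!any(ok)) return(NA_real_)
  pk <- which.max(curve)
  thr <- curve[pk] * level
  n <- length(curve)
  # walk outward from the peak to the first crossing on each side
  cross <- function(step) {
    prev <- pk
    for (k in seq_len(n - 1)) {
      i <- ((pk - 1 + step * k) %% n) + 1
      if (!is.na(curve[i]) && curve[i] < thr) {
        # linear interpolation between prev and i
        f <- (curve[prev] - thr) / (curve[prev] - curve[i])
        return(k - 1 + f)
      }
      prev <- i
    }
    NA_real_
  }
  up <- cross(1L); dn <- cross(-1L)
  if (is.na(up) || is.na(dn)) {
    warning("tuning width undefined: curve never falls below the level")
    return(NA_real_)
  }
  (up + dn) * (360 / n)
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> preferred %.0f deg, width %.1f deg (at %.0f%% of peak), peak %.2f Hz\n",
              deg(x$preferred), x$width_deg, 100 * x$width_level,
              max(x$smooth, na.rm = TRUE)))
  invisible(x)
}

#' Circular-linear correlation for theta phase precession
#'
#' Fits the slope that maximizes the mean resultant length of
#' `phase - 2*pi*a*x` over a bounded slope range, then computes the
#' circular-circular correlation between the observed phases and the fitted
#' linear phases (Kempter-style estimator). The coefficient is reported in
#' `[0, 1]` together with the signed fitted slope.
#'
#' @param phases Spike theta phases, radians.
#' @param covariate Numeric covariate (e.g. turning angle relative to the
#'   preferred direction, radians).
#' @param slope_range Search range for the slope, cycles per covariate unit.
#' @return A list of class `circlin_fit`: `rho` in `[0, 1]`, `slope`
#'   (cycles per unit, signed), and `rho_signed`.
#' @export
phase_precession_corr <- function(phases, covariate, slope_range = c(-3, 3)) {
  stopifnot(length(phases) == length(covariate))
  if (length(phases) < 10) stop("need at least 10 spikes")
  if (stats::sd(covariate) == 0) stop("degenerate covariate")
  Rfun <- function(a) -Mod(mean(exp(1i * (phases - 2 * pi * a * covariate))))
  grid <- seq(slope_range[1], slope_range[2], length.out = 401)
  a0 <- grid[which.min(vapply(grid, Rfun, numeric(1)))]
  half <- diff(slope_range) / 400
  a_hat <- stats::optimize(Rfun, c(a0 - half, a0 + half))$minimum
  psi <- (2 * pi * abs(a_hat) * covariate) %% (2 * pi)
  mu_phi <- circ_mean(phases); mu_psi <- circ_mean(psi)
  sp <- sin(phases - mu_phi); sq <- sin(psi - mu_psi)
  denom <- sqrt(sum(sp^2) * sum(sq^2))
  rho <- if (denom == 0) 0 else sum(sp * sq) / denom
  structure(list(rho = abs(rho), slope = a_hat, rho_signed = rho),
            class = "circlin_fit")
}

#' @export
print.circlin_fit <- function(x, ...) {
  cat(sprintf("<circlin_fit> rho = %.3f, slope = %.3f cycles/unit\n",
              x$rho, x$slope))
  invisible(x)
}

#' Theta-skipping index as a function of direction offset
#'
#' For spike trains recorded (or simulated) at fixed head directions, bins
#' cells by the unsigned offset between the head direction and the cell's
#' preferred internal direction, and fits the skipping model per cell. Cells
#' with fewer than `min_spikes` spikes are masked.
#'
#' @param trains List of `spike_train`s.
#' @param hd Fixed head direction per train, radians (recycled if length 1).
#' @param preferred_dirs Preferred direction per train, radians.
#' @param offset_breaks Breaks for the offset bins, degrees.
#' @param min_spikes Minimum spikes to attempt a fit.
#' @return A data frame with one row per cell (`offset_deg`, `TS`, `n_spikes`)
#'   and, as attribute `"binned"`, the per-bin mean TS with counts.
#' @export
skipping_vs_offset <- function(trains, hd, preferred_dirs,
                               offset_breaks = seq(0, 90, by = 15),
                               min_spikes = 50) {
  stopifnot(length(trains) == length(preferred_dirs))
  hd <- rep_len(hd, length(trains))
  rows <- lapply(seq_along(trains), function(i) {
    off <- deg(abs(wrap_angle(hd[i] - preferred_dirs[i])))
    nsp <- length(trains[[i]]$times)
    ts <- NA_real_
    if (nsp >= min_spikes) {
      ts <- try(fit_skipping_model(autocorrelogram(trains[[i]]))$TS,
                silent = TRUE)
      if (inherits(ts, "try-error")) ts <- NA_real_
    }
    data.frame(offset_deg = off, TS = ts, n_spikes = nsp)
  })
  out <- do.call(rbind, rows)
  bin <- cut(out$offset_deg, offset_breaks, include.lowest = TRUE)
  agg <- stats::aggregate(TS ~ bin, data = cbind(out, bin = bin),
                          FUN = mean, na.action = stats::na.omit)
  agg$n <- as.numeric(table(bin[!is.na(out$TS)])[as.character(agg$bin)])
  attr(out, "binned") <- agg
  out
}
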