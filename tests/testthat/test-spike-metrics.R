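test_that("Poisson spike generation is seeded, consistent, and validates input", {
  expect_length(poisson_spikes(rep(0, 1000), 1e-3, seed = 1)$times, 0)
  a <- poisson_spikes(rep(20, 5000), 1e-3, seed = 2)
  b <- poisson_spikes(rep(20, 5000), 1e-3, seed = 2)
  expect_identical(a$times, b$times)
  expect_error(poisson_spikes(c(-1, 2), 1e-3, seed = 1), "nonnegative")
  # constant 20 Hz for 100 s: count within 3 sigma of 2000
  tr <- poisson_spikes(rep(20, 1e5), 1e-3, seed = 3)
  expect_lt(abs(length(tr$times) - 2000), 3 * sqrt(2000))
})

test_that("autocorrelogram of a periodic train peaks at the period", {
  times <- seq(0, 20, by = 0.125)
  acg <- autocorrelogram(times)
  expect_length(acg$lag, 201)
  expect_equal(acg$value, rev(acg$value))  # symmetry
  at <- function(ms) acg$value[which.min(abs(acg$lag - ms / 1000))]
  expect_equal(at(125), 1)
  expect_gt(at(250), 0.9)
  expect_equal(at(60), 0)
  expect_error(autocorrelogram(c(1)), "insufficient")
})

test_that("homogeneous Poisson autocorrelogram is flat away from zero lag", {
  tr <- poisson_spikes(rep(30, 2e5), 1e-3, seed = 5)  # 200 s at 30 Hz
  acg <- autocorrelogram(tr)
  off <- acg$value[abs(acg$lag) > 0.03]
  expect_lt(stats::sd(off) / mean(off), 0.1)
  expect_true(all(acg$value <= 1))
})

test_that("skipping-model fit recovers known parameters within 1 percent", {
  truth <- c(a1 = 0.55, a2 = 0.25, b = 0.12, c = 0.5, omega = 12.5 * pi,
             tau1 = 0.45, tau2 = 0.003)
  acg <- make_acg_from_model(truth)
  fit <- fit_skipping_model(acg)
  for (nm in names(truth)) {
    expect_lt(abs(fit[[nm]] - truth[[nm]]) / truth[[nm]], 0.01,
              label = sprintf("parameter %s: fit %.4f truth %.4f", nm,
                              fit[[nm]], truth[[nm]]))
  }
  expect_lt(fit$fit_rss, 1e-4)
})

test_that("skipping index from constructed autocorrelograms has the right sign", {
  # theta-dominant: no skipping
  f1 <- fit_skipping_model(make_acg_from_model(
    c(a1 = 0.7, a2 = 0.02, b = 0.1, c = 0.4, omega = 14 * pi,
      tau1 = 0.5, tau2 = 0.003)))
  expect_lt(f1$TS, 0.1)
  # strong interfering oscillation at half frequency: skipping
  f2 <- fit_skipping_model(make_acg_from_model(
    c(a1 = 0.2, a2 = 0.6, b = 0.05, c = 0.4, omega = 14 * pi,
      tau1 = 0.5, tau2 = 0.003)))
  expect_gt(f2$TS, 0.1)
  expect_gt(f2$p2, f2$p1)
})

test_that("theta skipping index matches direct evaluation and bounds", {
  expect_equal(theta_skipping_index(0.8, 0.8), 0)
  expect_equal(theta_skipping_index(0.4, 0.8), 0.5)
  expect_equal(theta_skipping_index(1, 0), -1)
  expect_error(theta_skipping_index(0, 0), "undefined")
  set.seed(2)
  p1 <- runif(20); p2s <- sort(runif(20))
  ts <- sapply(p2s, function(p2) theta_skipping_index(0.5, p2))
  expect_true(all(diff(ts) >= 0))  # monotone in p2
  expect_true(all(abs(sapply(seq_along(p1), function(i)
    theta_skipping_index(p1[i], p2s[i]))) <= 1))
})

test_that("tuning width matches the von Mises closed form", {
  kappa <- 3
  om <- 50 * pi / 180
  tr <- make_rotation(om, 0, 6 * 2 * pi / om, dt = 1e-3, linear_speed = 0.3)
  rate <- 150 * exp(kappa * (cos(tr$theta_hd - 1) - 1))
  train <- poisson_spikes(rate, tr$t, seed = 8)
  for (lv in c(0.5, 0.2)) {
    tc <- tuning_curve(train, tr, smooth_sd = 4, width_level = lv)
    closed <- 2 * acos(1 + log(lv) / kappa) * 180 / pi
    expect_equal(tc$width_deg, closed, tolerance = 0.12)
  }
  tc <- tuning_curve(train, tr, smooth_sd = 4)
  expect_equal(wrap_angle(tc$preferred - 1), 0, tolerance = 0.15)
})

test_that("uniform firing has undefined tuning width", {
  tr <- make_rotation(1, 0, 20, dt = 1e-3, linear_speed = 0.3)
  train <- poisson_spikes(rep(20, nrow(tr)), tr$t, seed = 9)
  expect_warning(tc <- tuning_curve(train, tr), "undefined")
  expect_true(is.na(tc$width_deg))
})

test_that("circular-linear correlation: perfect relation, shuffle, degenerate input", {
  set.seed(12)
  x <- runif(300)
  ph <- (2 * pi * (-1.2) * x) %% (2 * pi)
  fit <- phase_precession_corr(ph, x)
  expect_gt(fit$rho, 0.99)
  expect_equal(fit$slope, -1.2, tolerance = 0.02)
  # shuffled phases: coefficient near zero (within the null band)
  null_rho <- replicate(30, phase_precession_corr(sample(ph), x)$rho)
  shuffled <- phase_precession_corr(sample(ph), x)
  expect_lt(shuffled$rho, quantile(null_rho, 0.99) + 0.1)
  expect_lt(median(null_rho), 0.2)
  expect_error(phase_precession_corr(ph, rep(1, 300)), "degenerate")
  expect_error(phase_precession_corr(ph[1:5], x[1:5]), "at least 10")
})

test_that("skipping_vs_offset bins cells and masks sparse ones", {
  # constructed trains: offset-independent skipping -> flat profile
  mk_skip_train <- function(seed) {
    # bursts every other theta cycle (8 Hz theta -> 250 ms burst period),
    # with occasional weak bursts on the skipped cycles
    set.seed(seed)
    strong <- rep(seq(0.05, 60, by = 0.25), each = 4)
    weak <- rep(seq(0.175, 60, by = 0.5), each = 1)
    sort(c(strong + rnorm(length(strong), 0, 0.02),
           weak + rnorm(length(weak), 0, 0.02)))
  }
  trains <- lapply(1:4, function(i) {
    structure(list(times = mk_skip_train(i), duration = 60),
              class = "spike_train")
  })
  prefs <- rad(c(5, 25, 50, 80))
  out <- skipping_vs_offset(trains, hd = 0, preferred_dirs = prefs,
                            offset_breaks = c(0, 30, 60, 90))
  expect_equal(nrow(out), 4)
  expect_true(all(out$TS > 0.1))
  expect_lt(diff(range(out$TS)), 0.2)  # flat
  # sparse train is masked
  trains[[2]]$times <- trains[[2]]$times[1:10]
  out2 <- skipping_vs_offset(trains, 0, prefs, offset_breaks = c(0, 30, 60, 90))
  expect_true(is.na(out2$TS[2]))
})
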