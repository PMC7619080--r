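test_that("ring distance is a wrapped metric", {
  expect_equal(ring_distance(0, pi), pi)
  expect_equal(ring_distance(0.1, 2 * pi - 0.1), 0.2)
  expect_equal(ring_distance(1.3, 1.3 + 2 * pi), 0)
  set.seed(1)
  a <- runif(50, -10, 10); b <- runif(50, -10, 10)
  expect_equal(ring_distance(a, b), ring_distance(b, a))
  expect_true(all(ring_distance(a, b) >= 0 & ring_distance(a, b) <= pi))
})

test_that("ring kernel is symmetric, translation-invariant, peaked on the diagonal", {
  p <- small_hd()
  J <- build_ring_kernel(p)
  expect_equal(J, t(J))
  expect_true(all(diag(J) == apply(J, 1, max)))
  expect_equal(max(rowSums(J)) - min(rowSums(J)), 0, tolerance = 1e-10)
  # every row is a rotation of the first
  expect_equal(J[2, c(2:p$N, 1)], J[1, ], tolerance = 1e-12)
})

test_that("theta gain follows the speed-scaled sinusoid", {
  p <- hd_params()
  expect_equal(theta_gain(0, 0.123, p$abar, p$omega_theta), 1)
  expect_equal(theta_gain(0.7, 0.123, 0, p$omega_theta), 1)
  expect_equal(theta_gain(0.5, 0, p$abar, p$omega_theta), 1)
  tq <- pi / 2 / p$omega_theta  # quarter period: sin = 1
  expect_equal(theta_gain(0.5, tq, p$abar, p$omega_theta),
               1 + 0.5 * p$abar)
})

test_that("directional input peaks at the head direction and scales with A", {
  p <- small_hd()
  x <- hd_pref_dirs(p$N)
  for (th in c(0.3, pi - 0.01, -2.5)) {
    i1 <- hd_input(th, 0.2, 0.05, p)
    expect_equal(which.max(i1), which.min(ring_distance(x, th)))
    expect_equal(hd_input(th + 2 * pi, 0.2, 0.05, p), i1)
  }
  p2 <- p; p2$A <- 2 * p$A
  expect_equal(hd_input(0.3, 0.2, 0.05, p2), 2 * hd_input(0.3, 0.2, 0.05, p))
})

test_that("divisive rates match direct evaluation", {
  expect_equal(divisive_rates(rep(0, 5), 1), rep(0, 5))
  h <- c(1.5, -2, 0.3)
  expect_equal(divisive_rates(h, 0), h^2)
  h1 <- c(3, 0, 0, 0)
  expect_equal(divisive_rates(h1, 1)[1], 9 / (1 + 9))
  expect_true(all(divisive_rates(rnorm(20), 0.4) >= 0))
})

test_that("step_hd fixed points and divergence detection", {
  p <- small_hd(m = 0)
  net <- hd_network(p)
  zero <- list(h = rep(0, p$N), a = rep(0, p$N), r = rep(0, p$N))
  s1 <- step_hd(net, zero, rep(0, p$N), 1e-3)
  expect_equal(s1$h, zero$h)
  expect_equal(s1$r, zero$r)
  # adaptation stays off when m = 0
  inp <- hd_input(0, 0, 0, p)
  s <- zero
  for (i in 1:50) s <- step_hd(net, s, inp, 1e-3)
  expect_equal(s$a, rep(0, p$N))
  bad <- list(h = c(NaN, rep(0, p$N - 1)), a = rep(0, p$N), r = rep(0, p$N))
  expect_error(step_hd(net, bad, inp, 1e-3), "'h'")
  expect_error(step_hd(net, zero, inp, p$tau))  # dt too large
})

test_that("with constant input and no adaptation the bump settles on the input peak", {
  p <- small_hd(m = 0, abar = 0)
  net <- hd_network(p)
  h0 <- hd_input(0, 0, 0, p)
  s <- list(h = h0, a = rep(0, p$N), r = divisive_rates(h0, p$k, 2 * pi / p$N))
  inp <- hd_input(1.1, 0, 0, p)
  for (i in seq_len(1000)) s <- step_hd(net, s, inp, 1e-3)  # 100 tau
  expect_lt(abs(wrap_angle(internal_direction(s$r, net$x) - 1.1)), 0.05)
})

test_that("internal_direction is exact on symmetric bumps and rejects flat fields", {
  x <- hd_pref_dirs(90)
  for (c0 in c(0.5, pi, -3, 0.02)) {  # includes bumps straddling the seam
    r <- make_bump_field(c0, 0.4, 90)
    expect_equal(wrap_angle(internal_direction(r, x) - c0), 0, tolerance = 1e-9)
  }
  expect_error(internal_direction(rep(1, 90), x), "undefined")
  expect_error(internal_direction(rep(0, 90), x), "undefined")
  # rotate-and-compare: shifting the field by k cells shifts the center
  r <- make_bump_field(0.9, 0.3, 90)
  r_shift <- r[c(31:90, 1:30)]
  d <- wrap_angle(internal_direction(r_shift, x) - internal_direction(r, x))
  expect_equal(d, -30 * 2 * pi / 90, tolerance = 1e-9)
})

test_that("tracking limit: without adaptation and theta the bump follows any trajectory", {
  p <- small_hd(m = 0, abar = 0)
  trs <- list(make_rotation(pi / 2, 0, 1.2, linear_speed = 0.3),
              make_random_walk(1.2, seed = 21,
                               turn_stats = list(sd = 1.5), arena_size = 4))
  for (tr in trs) {
    run <- run_hd(tr, p, warmup = 0.3)
    err <- abs(wrap_angle(run$center - tr$theta_hd))
    expect_lt(max(err, na.rm = TRUE), p$b)
  }
})

test_that("rates stay nonnegative and bounded; runs are deterministic", {
  tr <- make_straight_run(0.5, pi / 4, 0.6)
  run <- run_hd(tr, small_hd(), warmup = 0.2)
  expect_true(all(run$r >= 0))
  expect_true(all(is.finite(run$r)))
  # divisive normalization caps the total squared rate
  expect_true(max(run$pop_rate) < 1e3)
  run2 <- run_hd(tr, small_hd(), warmup = 0.2)
  expect_identical(run$r, run2$r)
})

test_that("Euler solution is converged: halving dt barely moves the bump trace", {
  p <- small_hd()
  tr1 <- make_straight_run(0.5, pi / 4, 0.8, dt = 1e-3)
  tr2 <- make_straight_run(0.5, pi / 4, 0.8, dt = 5e-4)
  r1 <- run_hd(tr1, p, warmup = 0.3)
  r2 <- run_hd(tr2, p, warmup = 0.3)
  c2 <- r2$center[seq(1, length(r2$center), by = 2)]
  d <- abs(wrap_angle(r1$center - c2))
  expect_lt(mean(d, na.rm = TRUE), 0.01 * pi)
})

test_that("network dynamics are invariant to the ring resolution", {
  tr <- make_straight_run(0.5, pi / 4, 0.6)
  r1 <- run_hd(tr, hd_params(N = 64), warmup = 0.3)
  r2 <- run_hd(tr, hd_params(N = 128), warmup = 0.3)
  d <- abs(wrap_angle(r1$center - r2$center))
  expect_lt(mean(d, na.rm = TRUE), 0.02)
  expect_equal(max(r1$r), max(r2$r), tolerance = 0.05)
})
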