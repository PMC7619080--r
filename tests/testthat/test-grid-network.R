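test_that("phase map: printed examples and hexagonal lattice invariance", {
  lam <- 0.3
  expect_equal(phase_map(c(0, 0), lam), c(0, 0))
  expect_lt(max(abs(wrap_angle(phase_map(c(lam, 0), lam)))), 1e-9)
  expect_lt(max(abs(wrap_angle(phase_map(c(lam / 2, lam * sqrt(3) / 2), lam)))),
            1e-9)
  set.seed(4)
  z <- matrix(runif(2000, -3, 3), ncol = 2)
  p0 <- phase_map(z, lam)
  p1 <- phase_map(sweep(z, 2, c(lam, 0), "+"), lam)
  p2 <- phase_map(sweep(z, 2, lam * c(1 / 2, sqrt(3) / 2), "+"), lam)
  wrapd <- function(a, b) abs(wrap_angle(a - b))
  expect_lt(max(wrapd(p1, p0)), 1e-9)
  expect_lt(max(wrapd(p2, p0)), 1e-9)
})

test_that("torus distance wraps componentwise", {
  expect_equal(torus_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(torus_distance(c(0, 0), c(2 * pi - 0.1, 0)), 0.1,
               tolerance = 1e-12)
  a <- c(0.3, 5.9); b <- c(6.1, 0.4)
  expect_equal(torus_distance(a, b), torus_distance(b, a))
  expect_equal(torus_distance(c(0, 0), c(pi, pi)), pi * sqrt(2))
})

test_that("FFT circular convolution equals the dense weight-matrix product", {
  p <- small_grid()
  net <- grid_network(p)
  n <- p$n_side
  # dense N x N weight matrix from circular shifts of the kernel
  K <- net$kernel * net$measure
  idx <- function(i, n) ((i - 1) %% n) + 1
  W <- matrix(0, n * n, n * n)
  for (i in 1:n) for (j in 1:n) {
    row <- (j - 1) * n + i
    block <- K[idx(1 + (1:n) - i, n), idx(1 + (1:n) - j, n)]
    W[row, ] <- as.vector(block)
  }
  set.seed(7)
  for (rep in 1:3) {
    f <- matrix(runif(n * n), n, n)
    dense <- matrix(W %*% as.vector(f), n, n)
    conv <- torus_convolve(f, net$kernel_fft)
    expect_lt(max(abs(dense - conv)), 1e-10)
  }
  # convolving a delta returns the kernel itself
  delta <- matrix(0, n, n); delta[1, 1] <- 1
  expect_lt(max(abs(torus_convolve(delta, net$kernel_fft) - K)), 1e-12)
})

test_that("speed gain is affine in running speed", {
  p <- grid_params()
  expect_equal(speed_gain(0, p), p$A)
  v <- c(0.2, 0.4, 0.8)
  expect_equal(speed_gain(2 * v, p) - speed_gain(v, p), p$T0 * v)
  expect_error(speed_gain(-1, p))
})

test_that("conjunctive input is a shifted bump along the internal direction", {
  p <- small_grid(w0 = 0, abar = 0)
  net <- grid_network(p)
  N_h <- 40
  xh <- hd_pref_dirs(N_h)
  beta <- xh[9]
  r_h <- rep(0, N_h); r_h[9] <- 1
  z <- c(0.13, 0.07)
  f0 <- conj_input(r_h, xh, z, 0.5, 0, net)
  psi <- phase_map(z, p$lambda)
  pk <- which(f0 == max(f0), arr.ind = TRUE)
  lat <- net$phi
  expect_lt(torus_distance(c(lat[pk[1]], lat[pk[2]]), psi), 2 * pi / p$n_side * 1.5)
  # with w0 > 0 the peak is displaced by w0 along beta
  p2 <- small_grid(w0 = 0.7, abar = 0)
  net2 <- grid_network(p2)
  f1 <- conj_input(r_h, xh, z, 0.5, 0, net2)
  pk1 <- which(f1 == max(f1), arr.ind = TRUE)
  target <- (psi + 0.7 * c(cos(beta), sin(beta))) %% (2 * pi)
  expect_lt(torus_distance(c(lat[pk1[1]], lat[pk1[2]]), target),
            2 * pi / p$n_side * 1.5)
  # immobility with zero baseline: no drive
  p3 <- small_grid(A = 0)
  net3 <- grid_network(p3)
  expect_equal(max(abs(conj_input(r_h, xh, z, 0, 0.1, net3))), 0)
  # zero HD rates: zero field with a warning
  expect_warning(f <- conj_input(rep(0, N_h), xh, z, 0.5, 0, net),
                 "zero")
  expect_equal(max(abs(f)), 0)
})

test_that("step_grid holds fixed points and stays finite and nonnegative", {
  p <- small_grid(m = 0)
  net <- grid_network(p)
  n <- p$n_side
  zero <- list(g = matrix(0, n, n), a = matrix(0, n, n), r = matrix(0, n, n))
  s1 <- step_grid(net, zero, matrix(0, n, n), 1e-3)
  expect_equal(s1$g, zero$g)
  # static centered input -> stationary bump at the input peak
  inp <- 0.5 * make_bump_field(c(pi, pi), p$b, n)
  s <- zero
  for (i in seq_len(800)) s <- step_grid(net, s, inp, 1e-3)
  ctr <- bump_center_torus(s$r)
  expect_lt(torus_distance(ctr, c(pi, pi)), 0.05)
  expect_true(all(s$r >= 0) && all(is.finite(s$r)))
})

test_that("coupled run tracks position when adaptation and theta are off", {
  tr <- make_straight_run(0.4, pi / 6, 1.2)
  hd <- small_hd(m = 0, abar = 0)
  gp <- grid_params(n_side = 24, m = 0.05, abar = 0, lambda = 0.4)
  run <- run_coupled(tr, hd, gp, warmup = 0.4)
  track <- decode_track(run)
  err <- sqrt((track$loc_x - tr$x)^2 + (track$loc_y - tr$y)^2)
  half_width <- sqrt(2) * gp$b * gp$lambda / (2 * pi)
  expect_lt(max(err[track$coherent]), half_width)
  derr <- abs(wrap_angle(track$internal_dir - tr$theta_hd))
  expect_lt(max(derr, na.rm = TRUE), hd$b)
})

test_that("coupled Euler solution is step-size and resolution converged", {
  hd <- hd_params()
  gp1 <- grid_params(n_side = 24)
  tr1 <- make_straight_run(0.5, pi / 4, 1, dt = 1e-3)
  tr2 <- make_straight_run(0.5, pi / 4, 1, dt = 5e-4)
  r1 <- run_coupled(tr1, hd, gp1, warmup = 0.4)
  r2 <- run_coupled(tr2, hd, gp1, warmup = 0.4)
  c1 <- r1$modules[[1]]$center
  c2 <- r2$modules[[1]]$center[seq(1, nrow(r2$modules[[1]]$center), by = 2), ]
  d <- torus_distance(c1, c2)
  expect_lt(mean(d, na.rm = TRUE), 0.01 * pi)
  # doubling the sheet resolution leaves the bump-center trace unchanged
  r3 <- run_coupled(tr1, hd, grid_params(n_side = 48), warmup = 0.4)
  d2 <- torus_distance(c1, r3$modules[[1]]$center)
  expect_lt(mean(d2, na.rm = TRUE), 0.05)
})

test_that("single-cell rate map on a space-filling walk is six-fold symmetric", {
  tr <- make_random_walk(40, dt = 2e-3, arena_size = 1,
                         speed_stats = list(mean = 0.35, sd = 0.05),
                         turn_stats = list(sd = 2.5), seed = 17)
  run <- run_coupled(tr, hd_params(), grid_params(n_side = 32, lambda = 0.35),
                     warmup = 0.4, probe_cells = c(1L))
  rate <- run$modules[[1]]$probe[, 1]
  bin_w <- 0.05
  bx <- pmin(pmax(ceiling(tr$x / bin_w), 1), 20)
  by <- pmin(pmax(ceiling(tr$y / bin_w), 1), 20)
  map <- matrix(NA_real_, 20, 20)
  agg <- tapply(rate, list(bx, by), mean)
  map[cbind(as.integer(rep(rownames(agg), ncol(agg))),
            as.integer(rep(colnames(agg), each = nrow(agg))))] <- as.vector(agg)
  expect_gt(gridness_score(map), 0)
})
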