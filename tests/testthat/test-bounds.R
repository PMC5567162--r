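test_that("forcing bound assembles the componentwise displacement maximum", {
  p <- p_tab1
  cg <- forcing_bound(p, input_alpha)
  expect_equal(cg, c(p$A * p$a * (0 + p$nu_max),
                     p$A * p$a * (220 + p$C2 * p$nu_max),
                     p$B * p$b * (0 + p$C4 * p$nu_max)))
  expect_true(all(cg > 0))
  expect_error(forcing_bound(p, jr_input(mu = c(-1, 220, 0))), "non-negative")
})

test_that("mean envelope collapses at t = 0 and converges to the stated limits", {
  p <- p_tab1
  x0 <- c(1, 2, 3, 4, 5, 6)
  e0 <- mean_envelope(0, x0, p, input_alpha)
  expect_equal(e0$lower, x0[1:3])
  expect_equal(e0$upper, x0[1:3])

  e5 <- mean_envelope(5, x0, p, input_alpha)
  expect_equal(e5$lower, rep(0, 3), tolerance = 1e-12)
  expect_equal(e5$upper, forcing_bound(p, input_alpha) / p$gamma^2,
               tolerance = 1e-10)

  e <- mean_envelope(seq(0, 1, by = 0.05), x0, p, input_alpha)
  expect_true(all(e$lower <= e$upper))
  expect_true(all(is.finite(e$upper)))
})

test_that("envelope variance agrees with the transition covariance across code paths", {
  p <- p_tab1
  for (t in c(0.01, 0.1, 0.5, 2)) {
    v_env <- jrnmm:::.envelope_parts(t, rep(0, 6), p, input_alpha, var = TRUE)$var[, 1]
    v_cov <- diag(ou_step_covariance(t, p, input_alpha))[1:3]
    expect_rel_equal(v_env, v_cov, 1e-10)
  }
})

test_that("second-moment envelope: degenerate cases, long-time limit, dominance", {
  # no forcing, no noise: the bound reduces to the squared free solution
  inp0 <- jr_input(mu = c(0, 0, 0), sigma = c(0, 0, 0))
  x0 <- c(1, -2, 3, 10, 0, -5)
  tt <- c(0.01, 0.1, 0.4)
  m2 <- second_moment_envelope(tt, x0, p_linear, inp0)
  u <- jrnmm:::.envelope_parts(tt, x0, p_linear, inp0)$u
  expect_equal(m2$upper, as.numeric(u^2), tolerance = 1e-12)

  # long-time limit matches the printed constant
  p <- p_tab1
  lim <- second_moment_envelope(10, rep(0, 6), p, input_alpha)
  cg <- forcing_bound(p, input_alpha)
  sig <- c(10, 1000, 10)
  expect_equal(lim$upper,
               (cg / p$gamma^2 + sig / (2 * p$gamma^1.5))^2, tolerance = 1e-8)

  # the bound dominates the squared lower mean envelope
  grid <- seq(0.01, 1, by = 0.01)
  env <- mean_envelope(grid, rep(0, 6), p, input_alpha)
  m2g <- second_moment_envelope(grid, rep(0, 6), p, input_alpha)
  expect_true(all(m2g$upper >= env$lower^2 - 1e-12))

  sig_t <- jr_input(sigma = list(10, function(t) 1000 + t, 10))
  expect_error(second_moment_envelope(1, rep(0, 6), p, sig_t), "constant")
})

test_that("escape bound is a calibrated Gaussian tail with the right degenerations", {
  p <- p_tab1
  t <- 0.5
  parts <- jrnmm:::.envelope_parts(t, rep(0, 6), p, input_alpha, var = TRUE)
  m <- parts$mean[2, 1]

  expect_equal(escape_bound(t, "x1", m, rep(0, 6), p, input_alpha), 0.5)
  expect_equal(escape_bound(t, "x1", 1e9, rep(0, 6), p, input_alpha), 0)

  s <- sqrt(parts$var[2, 1])
  ths <- m + seq(-3, 3, by = 0.25) * s
  bounds <- vapply(ths, function(th) {
    escape_bound(t, "x1", th, rep(0, 6), p, input_alpha)
  }, numeric(1))
  expect_true(all(diff(bounds) < 0))
  expect_true(all(bounds >= 0 & bounds <= 1))

  # integer component labels match the string labels
  expect_equal(escape_bound(t, 1, m, rep(0, 6), p, input_alpha),
               escape_bound(t, "x1", m, rep(0, 6), p, input_alpha))

  # zero noise degenerates to an indicator
  none <- jr_input(mu = c(0, 220, 0), sigma = c(0, 0, 0))
  m0 <- jrnmm:::.envelope_parts(t, rep(0, 6), p, none)$mean[2, 1]
  expect_equal(escape_bound(t, "x1", m0 - 1, rep(0, 6), p, none), 1)
  expect_equal(escape_bound(t, "x1", m0 + 1, rep(0, 6), p, none), 0)

  # empirical exceedance frequency respects the bound
  set.seed(31)
  ens <- jr_ensemble(p, input_alpha, rep(0, 6), t_end = 0.5, dt = 1e-3,
                     scheme = "wiener", n_paths = 1000, seed = 31,
                     record_times = 0.5)
  th <- jr_bound_curve(0.5, "x1", 0.9, rep(0, 6), p, input_alpha)
  eb <- escape_bound(0.5, "x1", th, rep(0, 6), p, input_alpha)
  expect_equal(eb, 0.1, tolerance = 1e-10)
  freq <- mean(ens$states[2, , 1] >= th)
  expect_lte(freq, eb + 3 * sqrt(eb * (1 - eb) / 1000))
})

test_that("noise calibration solves the quantile equation and is monotone", {
  p <- p_tab1
  t <- 0.5
  m <- jrnmm:::.envelope_parts(t, rep(0, 6), p, input_alpha)$mean[1, 1]
  th <- m + 0.5

  s95 <- calibrate_sigma("x0", t, th, 0.95, p, input_alpha)
  expect_gt(s95, 0)
  # round trip: the escape bound at the calibrated noise reproduces 1 - alpha
  inp95 <- jr_input(mu = c(0, 220, 0), sigma = c(s95, 1000, 10))
  expect_equal(escape_bound(t, "x0", th, rep(0, 6), p, inp95), 0.05,
               tolerance = 1e-8)

  # higher confidence at the same threshold requires weaker noise
  s90 <- calibrate_sigma("x0", t, th, 0.90, p, input_alpha)
  s99 <- calibrate_sigma("x0", t, th, 0.99, p, input_alpha)
  expect_lt(s99, s90)
  grid <- vapply(c(0.6, 0.75, 0.9, 0.99), function(a) {
    calibrate_sigma("x0", t, th, a, p, input_alpha)
  }, numeric(1))
  expect_true(all(diff(grid) < 0))

  # degenerate and infeasible cases
  expect_equal(calibrate_sigma("x0", t, m, 0.5, p, input_alpha), 0)
  expect_error(calibrate_sigma("x0", t, m - 1, 0.95, p, input_alpha),
               "no calibrated sigma")
})

test_that("convolution representation reconstructs stepped trajectories", {
  # pure linear flow: reconstruction is exact and equals theta Q0 + kappa P0
  x0 <- c(1, -1, 2, 5, 0, -3)
  tr0 <- jr_simulate(p_linear, input_zero, x0 = x0, t_end = 0.05, dt = 1e-3,
                     scheme = "wiener", seed = 1, keep_noise = TRUE)
  rec0 <- convolution_reconstruct(tr0)
  k <- jrnmm:::.kernels_vec(tr0$t, p_linear$gamma)
  free <- t(k$theta * x0[1:3] + k$kappa * x0[4:6])
  expect_equal(as.matrix(rec0[, c("x0", "x1", "x2")]), free,
               ignore_attr = TRUE, tolerance = 1e-12)

  # exact algebraic identity with the Wiener integrator, checked at 3 steps
  tr3 <- jr_simulate(p_tab1, input_alpha, t_end = 3e-3, dt = 1e-3,
                     scheme = "wiener", seed = 5, keep_noise = TRUE)
  rec3 <- convolution_reconstruct(tr3)
  expect_equal(as.matrix(rec3[, c("x0", "x1", "x2")]),
               as.matrix(tr3[, c("x0", "x1", "x2")]),
               ignore_attr = TRUE, tolerance = 1e-12)
  # ... and along a longer noisy run
  trn <- jr_simulate(p_tab1, input_alpha, t_end = 0.5, dt = 1e-3,
                     scheme = "wiener", seed = 6, keep_noise = TRUE)
  recn <- convolution_reconstruct(trn)
  expect_lt(max(abs(as.matrix(recn[, 2:4]) - as.matrix(trn[, c("x0", "x1", "x2")]))),
            1e-9)

  # first-order discrepancy against the Strang trajectory: halves with dt
  disc <- vapply(c(2e-3, 1e-3), function(dt) {
    tr <- jr_simulate(p_tab1, input_det, t_end = 0.5, dt = dt,
                      scheme = "strang", seed = 2, keep_noise = TRUE)
    rec <- convolution_reconstruct(tr)
    max(abs(as.matrix(rec[, 2:4]) - as.matrix(tr[, c("x0", "x1", "x2")])))
  }, numeric(1))
  expect_gt(disc[1] / disc[2], 1.5)
  expect_lt(disc[1] / disc[2], 3)

  # increments are required
  trx <- jr_simulate(p_tab1, input_alpha, t_end = 0.01, dt = 1e-3,
                     scheme = "wiener", seed = 1)
  expect_error(convolution_reconstruct(trx), "keep_noise")
})
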