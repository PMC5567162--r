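test_that("one-step covariance: zero noise, closed form vs ODE, long-time limit, PSD", {
  p <- p_tab1
  expect_equal(unclass(ou_step_covariance(0.002, p, input_det)),
               matrix(0, 6, 6), ignore_attr = TRUE)

  Cc <- ou_step_covariance(0.002, p, input_alpha, method = "closed")
  Co <- ou_step_covariance(0.002, p, input_alpha, method = "ode")
  expect_lt(max(abs(Cc - Co)) / max(abs(Cc)), 1e-8)

  # dt -> large: upper-left block approaches Gamma^{-3} Sigma^2 / 4
  Cbig <- ou_step_covariance(1, p, input_alpha)
  sig2 <- c(10, 1000, 10)^2
  expect_equal(diag(Cbig)[1:3], sig2 / (4 * p$gamma^3), tolerance = 1e-8)

  # PSD across step sizes, and the symmetric root round-trips
  for (dt in c(1e-5, 1e-4, 1e-3, 1e-2, 0.1, 1)) {
    C <- ou_step_covariance(dt, p, input_alpha)
    ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-12 * max(abs(ev)))
    B <- jrnmm:::.sym_sqrt(C)
    expect_lt(max(abs(B %*% B - C)) / max(abs(C)), 1e-10)
  }

  expect_error(ou_step_covariance(0, p, input_alpha), "positive")
  sig_t <- jr_input(sigma = list(10, function(t) 1000 * exp(-t), 10))
  expect_error(ou_step_covariance(0.01, p, sig_t, method = "closed"), "constant")
  Ct <- ou_step_covariance(0.01, p, sig_t)
  expect_equal(attr(Ct, "method"), "ode")
  expect_true(isSymmetric(unclass(Ct)))
})

test_that("with sigmoid and noise off every splitting step is the exact linear flow", {
  dt <- 2e-3
  E <- jr_expM(dt, p_linear)
  x <- c(0.3, -0.2, 0.5, 40, -10, 25)
  for (s in c("ou", "wiener", "strang")) {
    expect_equal(jr_step(x, 0, dt, s, p_linear, input_zero),
                 as.numeric(E %*% x), tolerance = 1e-13)
  }
})

test_that("noise-free Lie-Trotter maps equal the hand-composed sub-flows", {
  p <- p_tab1
  dt <- 1e-3
  x <- c(0.1, 6, 1, 10, 100, -20)

  # [2]-flow first: momentum kick, then the exact linear flow
  kick <- x
  disp <- jr_displacement(0, x[1:3], p, input_det)
  kick[4:6] <- kick[4:6] + dt * disp$GII + dt * disp$GI
  manual <- as.numeric(jr_expM(dt, p) %*% kick)

  expect_equal(jr_step_ou(x, 0, dt, p, input_det), manual, tolerance = 1e-13)
  expect_equal(jr_step_wiener(x, 0, dt, p, input_det), manual, tolerance = 1e-13)

  # commuted composition: linear flow first, then the kick
  lin <- as.numeric(jr_expM(dt, p) %*% x)
  kick2 <- lin
  disp2 <- jr_displacement(0, lin[1:3], p, input_det)
  kick2[4:6] <- kick2[4:6] + dt * disp2$GII + dt * disp2$GI
  expect_equal(jr_step_ou(x, 0, dt, p, input_det, commute = TRUE), kick2,
               tolerance = 1e-13)

  # Strang: half linear, kick, half linear
  h1 <- as.numeric(jr_expM(dt / 2, p) %*% x)
  disp3 <- jr_displacement(0, h1[1:3], p, input_det)
  h1[4:6] <- h1[4:6] + dt * disp3$GII + dt * disp3$GI
  strang <- as.numeric(jr_expM(dt / 2, p) %*% h1)
  expect_equal(jr_step_strang(x, 0, dt, p, input_det), strang, tolerance = 1e-13)
})

test_that("Euler-Maruyama step is the first-order Taylor map", {
  dt <- 1e-3
  # zero drift and noise: identity
  expect_equal(jr_step_em(rep(0, 6), 0, dt, p_linear, input_zero), rep(0, 6))
  # linear case: one step equals (I + M dt) x, which differs from the exact
  # flow at second order in dt
  x <- c(0.3, -0.2, 0.5, 40, -10, 25)
  em <- jr_step_em(x, 0, dt, p_linear, input_zero)
  expect_equal(em, as.numeric((diag(6) + jr_M(p_linear) * dt) %*% x),
               tolerance = 1e-13)
  exact <- as.numeric(jr_expM(dt, p_linear) %*% x)
  gap <- max(abs(em - exact))
  expect_gt(gap, 0)
  expect_lt(gap, 0.5 * max(abs(x)) * (max(p_linear$gamma) * dt)^2 * 10)
})

test_that("a single exact OU step from the origin has the predicted Gaussian law", {
  p <- p_tab1
  dt <- 2e-3
  n <- 2e4
  set.seed(42)
  X <- jr_step(matrix(0, 6, n), 0, dt, "ou", p, input_alpha)

  G0 <- jr_displacement(0, c(0, 0, 0), p, input_alpha)$G
  mean_th <- as.numeric(jr_expM(dt, p) %*% c(0, 0, 0, dt * G0))
  C_th <- ou_step_covariance(dt, p, input_alpha)

  se <- sqrt(diag(C_th) / n)
  expect_true(all(abs(rowMeans(X) - mean_th) <= 5 * se + 1e-12))
  v_emp <- apply(X, 1, stats::var)
  ok <- diag(C_th) > 0
  expect_true(all(abs(v_emp[ok] / diag(C_th)[ok] - 1) < 0.08))
})

test_that("trajectories are reproducible, on an exact grid, and fail loudly", {
  t1 <- jr_simulate(p_tab1, input_alpha, t_end = 0.2, dt = 1e-3, scheme = "ou",
                    seed = 99)
  t2 <- jr_simulate(p_tab1, input_alpha, t_end = 0.2, dt = 1e-3, scheme = "ou",
                    seed = 99)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(nrow(t1), 201)
  expect_lt(max(abs(diff(t1$t) - 1e-3)), 1e-12)
  expect_equal(t1$y, t1$x1 - t1$x2)

  expect_error(jr_simulate(p_tab1, input_alpha, scheme = "heun"))
  expect_error(jr_simulate(p_tab1, input_alpha, t_end = 0.0105, dt = 1e-3),
               "integer multiple")
})

test_that("the C = 135 drive produces alpha-band oscillation, noise-free a limit cycle", {
  sc <- jr_preset("alpha_C135")
  tr <- jr_simulate(sc$params, sc$input, t_end = 10, dt = 1e-3,
                    scheme = "strang", seed = 1)
  y <- tr$y[tr$t > 2]
  sp <- stats::spec.pgram(stats::ts(y, deltat = 1e-3), spans = 21,
                          detrend = TRUE, plot = FALSE)
  peak <- sp$freq[which.max(sp$spec)]
  expect_gte(peak, 8)
  expect_lte(peak, 12)

  # without noise the solution settles on a bounded oscillation
  trd <- jr_simulate(sc$params, input_det, t_end = 5, dt = 1e-3,
                     scheme = "strang")
  tail_y <- trd$y[trd$t > 3]
  expect_true(all(is.finite(tail_y)))
  expect_lt(max(abs(tail_y)), 50)
  expect_gt(diff(range(tail_y)), 0.5)
  crossings <- sum(diff(sign(tail_y - mean(tail_y))) != 0)
  expect_gte(crossings, 10)
})

test_that("ensemble means of all splitting schemes stay inside the analytic envelope", {
  sc <- jr_preset("alpha_C135")
  times <- seq(0.05, 0.5, by = 0.05)
  for (scheme in c("ou", "wiener", "strang")) {
    for (dt in c(1e-3, 2e-3, 5e-3)) {
      ens <- jr_ensemble(sc$params, sc$input, rep(0, 6), t_end = 0.5, dt = dt,
                         scheme = scheme, n_paths = 1000, seed = 7,
                         record_times = times)
      env <- mean_envelope(times, rep(0, 6), sc$params, sc$input)
      for (ti in seq_along(times)) {
        Qt <- ens$states[1:3, , ti]
        m <- rowMeans(Qt)
        se <- apply(Qt, 1, stats::sd) / sqrt(ens$n_paths)
        e <- env[env$t == times[ti], ]
        expect_true(all(m >= e$lower - 3 * se),
                    label = sprintf("%s dt=%g t=%g lower", scheme, dt, times[ti]))
        expect_true(all(m <= e$upper + 3 * se),
                    label = sprintf("%s dt=%g t=%g upper", scheme, dt, times[ti]))
      }
    }
  }
})

test_that("draw streams and increments are consistent across grids", {
  # coarse raw increments are exact sums of the fine ones
  set.seed(1)
  W <- matrix(rnorm(32 * 5), 32, 5)
  W2 <- jrnmm:::.aggregate_increments(W, 4)
  expect_equal(W2[1, ], colSums(W[1:4, ]))
  expect_equal(W2[8, ], colSums(W[29:32, ]))
  # aggregation is associative across dyadic levels
  expect_equal(jrnmm:::.aggregate_increments(jrnmm:::.aggregate_increments(W, 2), 2),
               W2)

  # a scheme run against itself with identical increments has error zero
  Wc <- lapply(1:3, function(i) matrix(rnorm(50 * 4, sd = sqrt(1e-3)), 50, 4))
  a <- jrnmm:::.run_coupled("wiener", p_tab1, input_alpha, rep(0, 6), 1e-3, Wc)
  b <- jrnmm:::.run_coupled("wiener", p_tab1, input_alpha, rep(0, 6), 1e-3, Wc)
  expect_identical(a, b)
})
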