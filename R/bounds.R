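# Analytic moment envelopes and Gaussian pathwise escape bounds. All bounds
# are componentwise over the three position coordinates (x0, x1, x2); the
# analogous momentum bounds are not provided.

.component_names <- c("x0", "x1", "x2")

.component_index <- function(component) {
  if (is.character(component)) {
    i <- match(component, .component_names)
    if (is.na(i)) stop("component must be one of \"x0\", \"x1\", \"x2\"")
    return(i)
  }
  if (is.numeric(component) && length(component) == 1 && component %in% 0:2) {
    return(as.integer(component) + 1L)
  }
  stop("component must be \"x0\"/\"x1\"/\"x2\" or an integer in 0:2")
}

#' Componentwise bound on the displacement forcing
#'
#' The constant vector dominating `G(t, Q)`:
#' `C_G = (A a (mu3_max + nu_max), A a (mu4_max + C2 nu_max),
#' B b (mu5_max + C4 nu_max))`. It enters every moment envelope.
#'
#' @param params a [jr_params()] object.
#' @param input a [jr_input()] object (its `mu_max` bounds are used).
#' @return Length-3 numeric vector.
#' @export
forcing_bound <- function(params = jr_params(), input = jr_input()) {
  m <- input$mu_max
  if (any(m < 0)) stop("the moment bounds require non-negative inputs mu")
  c(params$A * params$a * (m[1] + params$nu_max),
    params$A * params$a * (m[2] + params$C2 * params$nu_max),
    params$B * params$b * (m[3] + params$C4 * params$nu_max))
}

# kernel diagonals for a vector of times: list of 3 x m matrices
.kernels_vec <- function(t, g) {
  tm <- matrix(t, 3, length(t), byrow = TRUE)
  e <- exp(-g * tm)
  list(theta = e * (1 + g * tm),
       kappa = e * tm,
       theta_prime = -g^2 * e * tm,
       kappa_prime = e * (1 - g * tm))
}

# mean and variance ingredients of the dominating Gaussian envelope process:
# u(t), w(t) = Gamma^{-2}(I - theta) C_G, mean m = u + w, and the variance
# Sigma^2 Gamma^{-3} (I + kappa theta' - theta^2) / 4 (requires constant Sigma
# whenever var = TRUE). Each entry is a 3 x length(t) matrix.
.envelope_parts <- function(t, x0, params, input, var = FALSE) {
  stopifnot(all(t >= 0), length(x0) == 6)
  g <- params$gamma
  k <- .kernels_vec(t, g)
  Q0 <- x0[1:3]; P0 <- x0[4:6]
  u <- k$theta * Q0 + k$kappa * P0
  CG <- forcing_bound(params, input)
  w <- (1 - k$theta) / g^2 * CG
  out <- list(u = u, w = w, mean = u + w,
              shape = 1 + k$kappa * k$theta_prime - k$theta^2, k = k)
  if (var) {
    s2 <- .sigma_const(input)^2
    out$var <- s2 / (4 * g^3) * out$shape
  }
  out
}

#' Analytic envelope of the mean position
#'
#' Componentwise bounds on `E[Q(t)]`:
#' `theta(t) Q0 + kappa(t) P0 <= E[Q(t)] <= theta(t) Q0 + kappa(t) P0 +
#' Gamma^{-2} (I - theta(t)) C_G`. The lower curve decays exponentially to 0
#' and the upper curve to `Gamma^{-2} C_G`, so the long-run mean lies in
#' `[0, Gamma^{-2} C_G]` componentwise. Requires non-negative bounded inputs.
#'
#' @param t non-negative time(s), s.
#' @param x0 length-6 initial state.
#' @param params a [jr_params()] object.
#' @param input a [jr_input()] object.
#' @return A tibble with columns `t`, `component`, `lower`, `upper`.
#' @export
mean_envelope <- function(t, x0 = rep(0, 6), params = jr_params(),
                          input = jr_input()) {
  p <- .envelope_parts(t, x0, params, input)
  t_col <- rep(t, each = 3)
  comp_col <- rep(.component_names, length(t))
  tibble::tibble(t = t_col, component = comp_col,
                 lower = as.numeric(p$u),
                 upper = as.numeric(p$u + p$w))
}

#' Analytic upper envelope of the second moment of the position
#'
#' Componentwise bound on `E[Q(t)^2]` for constant diffusion:
#' `u^2 + 2 u 1+(u) w + (w + Gamma^{-3/2} Sigma sqrt(I + kappa theta' -
#' theta^2) / 2)^2` with `u, w` as in [mean_envelope()] and `1+` the
#' elementwise positive-part indicator. Its long-time limit is
#' `(Gamma^{-2} C_G + Gamma^{-3/2} Sigma 1 / 2)^2`.
#'
#' @inheritParams mean_envelope
#' @return A tibble with columns `t`, `component`, `upper`.
#' @export
second_moment_envelope <- function(t, x0 = rep(0, 6), params = jr_params(),
                                   input = jr_input()) {
  if (!input_has_constant_sigma(input)) {
    stop("the second-moment envelope requires a constant diffusion matrix")
  }
  g <- params$gamma
  p <- .envelope_parts(t, x0, params, input)
  sig <- .sigma_const(input)
  noise_term <- sig / (2 * g^1.5) * sqrt(pmax(p$shape, 0))
  m2 <- p$u^2 + 2 * p$u * (p$u > 0) * p$w + (p$w + noise_term)^2
  t_col <- rep(t, each = 3)
  comp_col <- rep(.component_names, length(t))
  tibble::tibble(t = t_col, component = comp_col, upper = as.numeric(m2))
}

#' Gaussian pathwise escape-probability bound
#'
#' Upper bound on the probability that a position coordinate exceeds a
#' threshold at time `t`: every path of `Q` is dominated by a Gaussian process
#' with mean `u(t) + Gamma^{-2}(I - theta(t)) C_G` and variance
#' `Sigma^2 Gamma^{-3} (I + kappa theta' - theta^2) / 4`, so
#' `P(X_i(t) >= x_th) <= 1 - F(x_th)` with `F` the corresponding normal cdf.
#' With zero noise on the component the bound degenerates to the indicator:
#' 1 when the threshold does not exceed the envelope mean, else 0.
#'
#' @param t non-negative time(s), s. Vectorised.
#' @param component `"x0"`, `"x1"` or `"x2"` (or 0, 1, 2).
#' @param threshold the threshold `x_th` (mV).
#' @param x0 length-6 initial state.
#' @param params a [jr_params()] object.
#' @param input a [jr_input()] object with constant diffusion.
#' @return Probability bound(s) in `[0, 1]`, same length as `t`.
#' @export
escape_bound <- function(t, component, threshold, x0 = rep(0, 6),
                         params = jr_params(), input = jr_input()) {
  i <- .component_index(component)
  p <- .envelope_parts(t, x0, params, input, var = TRUE)
  m <- p$mean[i, ]
  s <- sqrt(pmax(p$var[i, ], 0))
  out <- ifelse(s > 0,
                1 - stats::pnorm(threshold, mean = m, sd = s),
                as.numeric(threshold <= m))
  as.numeric(out)
}

#' Quantile curve of the dominating Gaussian envelope
#'
#' The threshold curve below which a position coordinate stays with
#' probability at least `level` at each fixed time:
#' `mean(t) + qnorm(level) * sd(t)` of the dominating Gaussian process of
#' [escape_bound()].
#'
#' @inheritParams escape_bound
#' @param level confidence level in (0, 1), e.g. 0.99.
#' @return Numeric threshold curve, same length as `t`.
#' @export
jr_bound_curve <- function(t, component, level, x0 = rep(0, 6),
                           params = jr_params(), input = jr_input()) {
  stopifnot(level > 0, level < 1)
  i <- .component_index(component)
  p <- .envelope_parts(t, x0, params, input, var = TRUE)
  as.numeric(p$mean[i, ] + stats::qnorm(level) * sqrt(pmax(p$var[i, ], 0)))
}

#' Calibrate a noise scale to a pathwise threshold
#'
#' Finds the noise amplitude `sigma` for the chosen component such that the
#' dominating Gaussian envelope satisfies `F(threshold) = alpha` at time `t`,
#' i.e. the coordinate stays below the threshold with probability at least
#' `alpha`. The envelope mean does not depend on `sigma`, so the equation has
#' at most one root in `sigma`, located by bracketed root finding
#' ([stats::uniroot()] on `[0, sigma_max]`) to relative tolerance 1e-10.
#' The degenerate case `alpha = 0.5` with the threshold equal to the envelope
#' mean is satisfied by every `sigma`; 0 is returned by convention.
#'
#' @param component `"x0"`, `"x1"` or `"x2"` (or 0, 1, 2).
#' @param t time (s), scalar.
#' @param threshold threshold (mV); must not be below the envelope mean when
#'   `alpha >= 0.5`.
#' @param alpha target confidence in (0, 1).
#' @param params a [jr_params()] object.
#' @param input a [jr_input()] object (its other noise scales are kept).
#' @param sigma_max upper end of the search bracket.
#' @return The calibrated noise scale (scalar).
#' @export
calibrate_sigma <- function(component, t, threshold, alpha,
                            params = jr_params(), input = jr_input(),
                            sigma_max = 1e7) {
  stopifnot(alpha > 0, alpha < 1, length(t) == 1, t > 0)
  i <- .component_index(component)
  p <- .envelope_parts(t, x0 = rep(0, 6), params, input)
  m <- p$mean[i, 1]
  shape <- max(p$shape[i, 1], 0)
  g <- params$gamma[i]
  unit_sd <- sqrt(shape) / (2 * g^1.5)   # envelope sd per unit sigma

  if (threshold == m && alpha == 0.5) return(0)
  if (unit_sd == 0) stop("the envelope variance does not respond to sigma at this t")
  f <- function(sigma) stats::pnorm(threshold, mean = m, sd = sigma * unit_sd) - alpha
  lo <- (threshold >= m) - alpha         # limit sigma -> 0+
  hi <- f(sigma_max)
  if (sign(lo) == sign(hi)) {
    stop(sprintf(paste0("no calibrated sigma in [0, %g]: threshold %.4g vs envelope ",
                        "mean %.4g at t = %g with alpha = %g"),
                 sigma_max, threshold, m, t, alpha))
  }
  root <- stats::uniroot(f, lower = 0, upper = sigma_max,
                         tol = 1e-10 * max(1, sigma_max * 1e-6))$root
  # polish with the closed-form inverse for the round-trip contract
  q <- stats::qnorm(alpha)
  if (q != 0) root <- (threshold - m) / (q * unit_sd)
  root
}

#' Reconstruct the position path from the convolution representation
#'
#' Independent oracle for stepped trajectories: the position component solves
#' `Q(t) = theta(t) Q0 + kappa(t) P0 + int_0^t kappa(t - s) G(s, Q(s)) ds +
#' int_0^t kappa(t - s) Sigma dW(s)`. Both integrals are discretised with the
#' left-endpoint rectangle rule on the trajectory's own grid (first-order
#' accurate), reusing the stored momentum noise increments. For the Wiener
#' splitting this reconstruction coincides with the stepped path as an exact
#' algebraic identity; for the other schemes the discrepancy vanishes at
#' order `dt`.
#'
#' @param trajectory a `jr_trajectory` simulated with `keep_noise = TRUE`
#'   (schemes `"wiener"`, `"strang"` or `"em"`).
#' @return A tibble with columns `t`, `x0`, `x1`, `x2`: the reconstructed
#'   position path on the trajectory's grid.
#' @export
convolution_reconstruct <- function(trajectory) {
  stopifnot(inherits(trajectory, "jr_trajectory"))
  W <- attr(trajectory, "noise")
  if (is.null(W)) {
    stop("trajectory was not simulated with keep_noise = TRUE (or used the ou scheme)")
  }
  params <- attr(trajectory, "params")
  input <- attr(trajectory, "input")
  x0 <- attr(trajectory, "x0_init")
  tgrid <- trajectory$t
  N <- length(tgrid) - 1L
  dt <- attr(trajectory, "dt")
  g <- params$gamma

  Q <- t(as.matrix(trajectory[, c("x0", "x1", "x2")]))  # 3 x (N+1)
  GII <- .GII(Q[, 1:N, drop = FALSE], params)
  intGI <- vapply(tgrid[1:N], function(s) .int_GI(input, params, s, dt),
                  numeric(3))
  kick <- GII * dt + intGI + W                           # 3 x N

  # kernel weights kappa_c(t_i - t_k) at left endpoints t_k; clamping the
  # time differences at zero kills all non-causal entries since kappa(0) = 0
  D <- outer(tgrid, tgrid[1:N], "-")
  D[D < 0] <- 0
  rec <- matrix(0, N + 1, 3)
  k <- .kernels_vec(tgrid, g)
  for (c in 1:3) {
    K <- exp(-g[c] * D) * D
    rec[, c] <- k$theta[c, ] * x0[c] + k$kappa[c, ] * x0[c + 3] +
      as.numeric(K %*% kick[c, ])
  }
  tibble::tibble(t = tgrid, x0 = rec[, 1], x1 = rec[, 2], x2 = rec[, 3])
}

#' Envelope report with Monte-Carlo verification
#'
#' Computes the analytic mean envelope and second-moment envelope on a grid of
#' times and overlays ensemble Monte-Carlo estimates of `E[Q]` and `E[Q^2]`
#' with standard errors, one row per (time, component).
#'
#' @inheritParams jr_ensemble
#' @param times record times (on the step grid).
#' @return A tibble with columns `t`, `component`, `lower`, `upper`,
#'   `mc_mean`, `mc_se`, `m2_upper`, `mc_m2`, `mc_m2_se`.
#' @export
envelope_report <- function(params = jr_params(), input = jr_input(),
                            x0 = rep(0, 6), times = seq(0.1, 1, by = 0.1),
                            dt = 1e-3, scheme = "strang", n_paths = 2000,
                            seed = NULL) {
  ens <- jr_ensemble(params, input, x0, t_end = max(times), dt = dt,
                     scheme = scheme, n_paths = n_paths, seed = seed,
                     record_times = times)
  env <- mean_envelope(times, x0, params, input)
  m2 <- second_moment_envelope(times, x0, params, input)
  n <- ens$n_paths
  rows <- lapply(seq_along(times), function(ti) {
    Qt <- ens$states[1:3, , ti, drop = FALSE][, , 1]
    tibble::tibble(t = times[ti], component = .component_names,
                   mc_mean = rowMeans(Qt),
                   mc_se = apply(Qt, 1, stats::sd) / sqrt(n),
                   mc_m2 = rowMeans(Qt^2),
                   mc_m2_se = apply(Qt^2, 1, stats::sd) / sqrt(n))
  })
  mc <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(env, m2, by = c("t", "component"))
  out <- dplyr::rename(out, m2_upper = "upper.y", upper = "upper.x")
  dplyr::left_join(out, mc, by = c("t", "component"))
}

#' Plot an envelope report
#'
#' @param object a tibble produced by [envelope_report()].
#' @param ... unused.
#' @return A ggplot object: analytic mean envelopes with Monte-Carlo means.
#' @export
plot_envelope_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mc_mean), colour = "blue") +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "mean position (mV)",
                  title = "Monte-Carlo means inside analytic envelopes")
}
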