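# Internal stepping machinery. All steppers act on a 6 x n matrix of states
# (columns are independent paths) so that Monte-Carlo ensembles advance in
# vectorised form. The diagonal structure of the linear flow means every
# matrix product reduces to elementwise products with length-3 diagonals.
#
# The internal one-step maps take the *scaled* Gaussian increment: the 6-dim
# Ornstein-Uhlenbeck increment xi ~ N(0, Cov(dt)) for "ou", and the momentum
# increment Sigma dW (3 x n) for "wiener"/"strang"/"em". This lets convergence
# studies drive every scheme from one shared Brownian path.

.schemes <- c("strang", "ou", "wiener", "em")

# per-run context: everything that depends only on (params, input, dt, scheme)
.ctx_new <- function(params, input, dt, scheme, commute = FALSE,
                     need_cov = TRUE) {
  scheme <- match.arg(scheme, .schemes)
  ctx <- list(params = params, input = input, dt = dt, scheme = scheme,
              commute = commute, g = params$gamma,
              k_full = jr_kernel_blocks(dt, params),
              k_half = jr_kernel_blocks(dt / 2, params),
              mu_all_const = all(input$mu_const),
              sigma_const = input_has_constant_sigma(input))
  scale <- c(params$A * params$a, params$A * params$a, params$B * params$b)
  if (ctx$mu_all_const) {
    ctx$gi_rate <- scale * vapply(input$mu, identity, numeric(1))
  }
  if (ctx$sigma_const) {
    ctx$sig <- input$sigma_values
    ctx$w_sd <- ctx$sig * sqrt(dt)       # increment sd of the Wiener sub-flow
  }
  if (scheme == "ou" && need_cov) {
    ctx$ou_cov <- ou_step_covariance(dt, params, input)
    ctx$ou_root <- .sym_sqrt(ctx$ou_cov)
  }
  ctx
}

# apply the exact linear flow e^{M h} given its kernel blocks
.lin_apply <- function(k, X) {
  Q <- X[1:3, , drop = FALSE]
  P <- X[4:6, , drop = FALSE]
  rbind(k$theta * Q + k$kappa * P,
        k$theta_prime * Q + k$kappa_prime * P)
}

# integral of G^I over [t, t + h]
.ctx_int_GI <- function(ctx, t, h) {
  if (ctx$mu_all_const) ctx$gi_rate * h else .int_GI(ctx$input, ctx$params, t, h)
}

# nonlinear (+ optional noise) kick of the momentum: the [2]-sub-flow over h
.kick <- function(ctx, X, t, h, noise = NULL) {
  X[4:6, ] <- X[4:6, , drop = FALSE] +
    h * .GII(X[1:3, , drop = FALSE], ctx$params) +
    .ctx_int_GI(ctx, t, h) +
    if (is.null(noise)) 0 else noise
  X
}

# standard-normal draw matrix for one step (d x n)
.std_draws <- function(d, n) matrix(stats::rnorm(d * n), d, n)

# sd of the Wiener-sub-flow increment over [t, t + dt] (length 3)
.wiener_sd <- function(ctx, t) {
  if (ctx$sigma_const) return(ctx$w_sd)
  v <- vapply(1:3, function(i) {
    f <- ctx$input$sigma[[i]]
    if (ctx$input$sigma_const[i]) {
      ctx$input$sigma_values[i]^2 * ctx$dt
    } else {
      s <- t + .gl5$nodes * ctx$dt
      ctx$dt * sum(.gl5$weights * vapply(s, f, numeric(1))^2)
    }
  }, numeric(1))
  sqrt(v)
}

# one step of each scheme given the scaled increment

.step_ou <- function(ctx, X, t, xi) {
  if (ctx$commute) {
    X <- .lin_apply(ctx$k_full, X) + xi
    .kick(ctx, X, t, ctx$dt)
  } else {
    X <- .kick(ctx, X, t, ctx$dt)
    .lin_apply(ctx$k_full, X) + xi
  }
}

.step_wiener <- function(ctx, X, t, noise) {
  if (ctx$commute) {
    .kick(ctx, .lin_apply(ctx$k_full, X), t, ctx$dt, noise)
  } else {
    .lin_apply(ctx$k_full, .kick(ctx, X, t, ctx$dt, noise))
  }
}

.step_strang <- function(ctx, X, t, noise) {
  X <- .lin_apply(ctx$k_half, X)
  X <- .kick(ctx, X, t, ctx$dt, noise)
  .lin_apply(ctx$k_half, X)
}

.step_em <- function(ctx, X, t, noise) {
  g <- ctx$g
  dt <- ctx$dt
  Q <- X[1:3, , drop = FALSE]
  P <- X[4:6, , drop = FALSE]
  mu <- .mu_at(ctx$input, t)
  p <- ctx$params
  GI <- c(p$A * p$a * mu[1], p$A * p$a * mu[2], p$B * p$b * mu[3])
  rbind(Q + dt * P,
        P + dt * (-g^2 * Q - 2 * g * P + GI + .GII(Q, p)) +
          if (is.null(noise)) 0 else noise)
}

.step_fun <- function(scheme) {
  switch(scheme,
         ou = .step_ou, wiener = .step_wiener,
         strang = .step_strang, em = .step_em)
}

.draw_dim <- function(scheme) if (scheme == "ou") 6L else 3L

# scaled increment from standard-normal draws Z
.scale_draws <- function(ctx, t, Z) {
  if (ctx$scheme == "ou") ctx$ou_root %*% Z else .wiener_sd(ctx, t) * Z
}

#' Advance the model by one step of a splitting or Euler-Maruyama scheme
#'
#' One application of the chosen one-step map to a state (or a matrix of
#' states, one column per path). The Lie-Trotter maps compose the exactly
#' solved sub-flows: for `"ou"` the deterministic displacement kick acts
#' first, then the exact Ornstein-Uhlenbeck transition
#' `X <- e^{M dt} X + xi` with `xi ~ N(0, Cov(dt))`; for `"wiener"` the kick
#' also carries the Gaussian increment `Sigma dW` and the linear flow is
#' deterministic. `"strang"` symmetrises the Wiener variant with half steps of
#' the linear flow (a second-order map for the noise-free model). `"em"` is
#' the Euler-Maruyama baseline. Setting `commute = TRUE` reverses the order of
#' the two Lie-Trotter sub-flows (the theoretical guarantees hold for either
#' order).
#'
#' @param state length-6 state `(Q, P)` or a 6 x n matrix of states.
#' @param t current time (s).
#' @param dt step size (s).
#' @param scheme one of `"strang"`, `"ou"`, `"wiener"`, `"em"`.
#' @param params a [jr_params()] object.
#' @param input a [jr_input()] object.
#' @param draws optional matrix of standard-normal draws (6 x n for `"ou"`,
#'   3 x n otherwise); drawn internally when `NULL`.
#' @param commute reverse the Lie-Trotter composition order.
#' @return The advanced state, same shape as `state`.
#' @examples
#' p <- jr_params(); inp <- jr_input(sigma = c(0, 0, 0))
#' jr_step(rep(0, 6), t = 0, dt = 1e-3, scheme = "strang", p, inp)
#' @export
jr_step <- function(state, t, dt, scheme = "strang", params = jr_params(),
                    input = jr_input(), draws = NULL, commute = FALSE) {
  vec <- !is.matrix(state)
  X <- if (vec) matrix(state, 6, 1) else state
  stopifnot(nrow(X) == 6, all(is.finite(X)))
  ctx <- .ctx_new(params, input, dt, scheme, commute)
  d <- .draw_dim(ctx$scheme)
  if (is.null(draws)) draws <- .std_draws(d, ncol(X))
  if (!is.matrix(draws)) draws <- matrix(draws, d, ncol(X))
  stopifnot(nrow(draws) == d, ncol(draws) == ncol(X))
  out <- .step_fun(ctx$scheme)(ctx, X, t, .scale_draws(ctx, t, draws))
  if (vec) as.numeric(out) else out
}

#' @rdname jr_step
#' @export
jr_step_ou <- function(state, t, dt, params = jr_params(), input = jr_input(),
                       draws = NULL, commute = FALSE) {
  jr_step(state, t, dt, "ou", params, input, draws, commute)
}

#' @rdname jr_step
#' @export
jr_step_wiener <- function(state, t, dt, params = jr_params(),
                           input = jr_input(), draws = NULL, commute = FALSE) {
  jr_step(state, t, dt, "wiener", params, input, draws, commute)
}

#' @rdname jr_step
#' @export
jr_step_strang <- function(state, t, dt, params = jr_params(),
                           input = jr_input(), draws = NULL) {
  jr_step(state, t, dt, "strang", params, input, draws)
}

#' @rdname jr_step
#' @export
jr_step_em <- function(state, t, dt, params = jr_params(), input = jr_input(),
                       draws = NULL) {
  jr_step(state, t, dt, "em", params, input, draws)
}
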