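#' Physiological parameter set of the Jansen-Rit neural mass model
#'
#' Constructs the twelve physiological constants of the model. Time is
#' measured in seconds throughout the package, so the classical excitatory
#' and inhibitory time constants of 10 ms and 20 ms correspond to the rate
#' constants `a = 100` and `b = 50` (1/s). The four connectivity counts are
#' by default tied to the single average synapse number `C` through the
#' classical proportions `C1 = C`, `C2 = 0.8 C`, `C3 = C4 = 0.25 C`, but each
#' can be overridden individually.
#'
#' @param C average number of synapses between the populations (dimensionless).
#' @param A average excitatory synaptic gain (mV).
#' @param B average inhibitory synaptic gain (mV).
#' @param a reciprocal time constant of the excitatory postsynaptic potential (1/s).
#' @param b reciprocal time constant of the inhibitory postsynaptic potential (1/s).
#' @param C1,C2,C3,C4 connectivity counts (dimensionless, default proportional to `C`).
#' @param nu_max maximum firing rate of the populations (1/s).
#' @param v0 membrane potential at which half the maximum firing rate is attained (mV).
#' @param r slope of the sigmoid gain at `v0` (1/mV).
#'
#' @return An object of class `jr_params`: a named list of the constants plus
#'   the damping diagonal `gamma = c(a, a, b)`.
#' @examples
#' p <- jr_params()           # classical values, C = 135
#' p68 <- jr_params(C = 68)   # weaker coupling
#' @export
jr_params <- function(C = 135, A = 3.25, B = 22, a = 100, b = 50,
                      C1 = C, C2 = 0.8 * C, C3 = 0.25 * C, C4 = 0.25 * C,
                      nu_max = 5, v0 = 6, r = 0.56) {
  vals <- c(C = C, A = A, B = B, a = a, b = b, C1 = C1, C2 = C2, C3 = C3,
            C4 = C4, nu_max = nu_max, v0 = v0, r = r)
  if (!all(is.finite(vals))) stop("all model parameters must be finite")
  if (a <= 0 || b <= 0) stop("rate constants a and b must be strictly positive")
  if (nu_max < 0) stop("nu_max must be non-negative")
  if (r <= 0) stop("sigmoid slope r must be strictly positive")
  if (any(c(C1, C2, C3, C4) < 0)) stop("connectivity constants must be non-negative")
  p <- list(C = C, A = A, B = B, a = a, b = b,
            C1 = C1, C2 = C2, C3 = C3, C4 = C4,
            nu_max = nu_max, v0 = v0, r = r,
            gamma = c(a, a, b))
  class(p) <- "jr_params"
  p
}

#' @export
print.jr_params <- function(x, ...) {
  cat("<jr_params> Jansen-Rit model parameters\n")
  cat(sprintf("  A = %g mV, B = %g mV, a = %g 1/s, b = %g 1/s\n", x$A, x$B, x$a, x$b))
  cat(sprintf("  C = %g (C1 = %g, C2 = %g, C3 = %g, C4 = %g)\n",
              x$C, x$C1, x$C2, x$C3, x$C4))
  cat(sprintf("  nu_max = %g 1/s, v0 = %g mV, r = %g 1/mV\n", x$nu_max, x$v0, x$r))
  invisible(x)
}

.as_input_entry <- function(x, name) {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1 && is.finite(x)) return(x)
  stop(sprintf("%s must be a finite scalar or a function of time", name))
}

#' External input specification: deterministic drive and noise scales
#'
#' Bundles the three deterministic input functions `mu3, mu4, mu5` (entering
#' the displacement as firing-rate offsets, 1/s scale) and the three noise
#' amplitudes `sigma3, sigma4, sigma5` acting on the momentum components.
#' Entries may be constants or functions of time; any functional `mu` must
#' declare a finite upper bound (needed by the analytic moment envelopes),
#' passed through `mu_max`.
#'
#' @param mu length-3 numeric vector, or list of 3 entries each a scalar or a
#'   function of time: the deterministic inputs (mu3, mu4, mu5).
#' @param sigma length-3 numeric vector (non-negative), or list of 3 entries
#'   each a scalar or function of time: the noise scales (sigma3, sigma4, sigma5).
#' @param mu_max length-3 numeric vector of upper bounds for `mu`; required for
#'   functional entries, inferred as the value itself for constants.
#'
#' @return An object of class `jr_input`.
#' @examples
#' jr_input()                                     # alpha-rhythm drive of the C presets
#' jr_input(mu = c(0, 220, 0), sigma = c(0, 0, 0)) # deterministic model
#' @export
jr_input <- function(mu = c(0, 220, 0), sigma = c(10, 1000, 10), mu_max = NULL) {
  if (is.numeric(mu)) mu <- as.list(mu)
  if (is.numeric(sigma)) sigma <- as.list(sigma)
  stopifnot(length(mu) == 3, length(sigma) == 3)
  names(mu) <- names(sigma) <- c("3", "4", "5")
  mu <- lapply(seq_along(mu), function(i) .as_input_entry(mu[[i]], paste0("mu", i + 2)))
  sigma <- lapply(seq_along(sigma), function(i) .as_input_entry(sigma[[i]], paste0("sigma", i + 2)))

  mu_const <- vapply(mu, is.numeric, logical(1))
  sigma_const <- vapply(sigma, is.numeric, logical(1))

  if (is.null(mu_max)) {
    if (!all(mu_const)) {
      stop("mu_max must be supplied when any mu entry is a function of time")
    }
    mu_max <- vapply(mu, identity, numeric(1))
  }
  stopifnot(length(mu_max) == 3, all(is.finite(mu_max)))

  sv <- rep(NA_real_, 3)
  sv[sigma_const] <- vapply(sigma[sigma_const], identity, numeric(1))
  if (any(sv[sigma_const] < 0)) stop("constant noise scales must be non-negative")

  inp <- list(mu = mu, sigma = sigma,
              mu_const = mu_const, sigma_const = sigma_const,
              mu_max = as.numeric(mu_max), sigma_values = sv)
  class(inp) <- "jr_input"
  inp
}

#' @export
print.jr_input <- function(x, ...) {
  fmt <- function(v, const) {
    vapply(seq_along(v), function(i) {
      if (const[i]) format(v[[i]]) else "f(t)"
    }, character(1))
  }
  cat("<jr_input>\n")
  cat("  mu    =", paste(fmt(x$mu, x$mu_const), collapse = ", "), "\n")
  cat("  sigma =", paste(fmt(x$sigma, x$sigma_const), collapse = ", "), "\n")
  cat("  fully elliptic:", input_is_elliptic(x), "\n")
  invisible(x)
}

#' Is the noise fully elliptic?
#'
#' TRUE when all three noise scales are strictly positive constants, the
#' hypothesis under which the model has a unique invariant measure and is
#' geometrically ergodic.
#'
#' @param input a [jr_input()] object.
#' @return Logical scalar.
#' @export
input_is_elliptic <- function(input) {
  stopifnot(inherits(input, "jr_input"))
  all(input$sigma_const) && all(input$sigma_values > 0)
}

#' Is the diffusion matrix constant in time?
#' @param input a [jr_input()] object.
#' @return Logical scalar.
#' @export
input_has_constant_sigma <- function(input) {
  stopifnot(inherits(input, "jr_input"))
  all(input$sigma_const)
}

# deterministic input values at time t (length-3)
.mu_at <- function(input, t) {
  vapply(1:3, function(i) {
    if (input$mu_const[i]) input$mu[[i]] else input$mu[[i]](t)
  }, numeric(1))
}

# noise scales at time t (length-3)
.sigma_at <- function(input, t) {
  vapply(1:3, function(i) {
    if (input$sigma_const[i]) input$sigma[[i]] else input$sigma[[i]](t)
  }, numeric(1))
}

# constant noise scales, error when time dependent
.sigma_const <- function(input) {
  if (!input_has_constant_sigma(input)) {
    stop("this operation requires a constant diffusion matrix Sigma")
  }
  input$sigma_values
}

# 5-point Gauss-Legendre nodes/weights on [0, 1]
.gl5 <- local({
  x <- c(-0.906179845938664, -0.538469310105683, 0,
         0.538469310105683, 0.906179845938664)
  w <- c(0.236926885056189, 0.478628670499366, 0.568888888888889,
         0.478628670499366, 0.236926885056189)
  list(nodes = (x + 1) / 2, weights = w / 2)
})

# integral of the deterministic forcing G^I over [t, t + h]:
# (A a int mu3, A a int mu4, B b int mu5)
.int_GI <- function(input, params, t, h) {
  scale <- c(params$A * params$a, params$A * params$a, params$B * params$b)
  vapply(1:3, function(i) {
    if (input$mu_const[i]) {
      scale[i] * input$mu[[i]] * h
    } else {
      f <- input$mu[[i]]
      s <- t + .gl5$nodes * h
      scale[i] * h * sum(.gl5$weights * vapply(s, f, numeric(1)))
    }
  }, numeric(1))
}
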