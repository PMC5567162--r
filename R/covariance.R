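#' One-step covariance of the Ornstein-Uhlenbeck sub-flow
#'
#' Covariance matrix of the exact Gaussian increment
#' `xi(dt) = int_0^dt e^{M(dt - s)} S(s) dW(s)` of the linear-plus-noise
#' subsystem. For a constant diffusion matrix the closed form is used, with
#' diagonal blocks
#' `Cov_QQ = Gamma^{-3} Sigma^2 (I + kappa theta' - theta^2) / 4`,
#' `Cov_QP = Sigma^2 kappa^2 / 2` and
#' `Cov_PP = Gamma^{-1} Sigma^2 (I + kappa theta' - kappa'^2) / 4`,
#' all evaluated at `dt`. For time-dependent noise the matrix-valued ODE
#' `dC/dt = M C + C M' + diag(0, Sigma^2(t))`, `C(0) = 0`, is integrated once
#' with a fixed-step classical Runge-Utta scheme (`deSolve`, method `"rk4"`,
#' `substeps` steps); within a simulation the result is computed once per
#' step-size and reused for every step.
#'
#' @param dt step size (s), positive.
#' @param params a [jr_params()] object.
#' @param input a [jr_input()] object.
#' @param method `"closed"` (constant noise only) or `"ode"`; the default picks
#'   the closed form whenever the diffusion matrix is constant.
#' @param substeps number of fixed RK4 steps for the ODE route.
#' @return A 6 x 6 covariance matrix with attributes `dt` and `method`.
#' @export
ou_step_covariance <- function(dt, params = jr_params(), input = jr_input(),
                               method = NULL, substeps = 100) {
  if (!(is.numeric(dt) && length(dt) == 1 && dt > 0)) {
    stop("dt must be a positive scalar")
  }
  const_sig <- input_has_constant_sigma(input)
  if (is.null(method)) method <- if (const_sig) "closed" else "ode"
  method <- match.arg(method, c("closed", "ode"))
  if (method == "closed" && !const_sig) {
    stop("the closed form requires a constant diffusion matrix; use method = \"ode\"")
  }

  if (method == "closed") {
    g <- params$gamma
    s2 <- .sigma_const(input)^2
    k <- jr_kernel_blocks(dt, params)
    common <- 1 + k$kappa * k$theta_prime - k$theta^2
    cqq <- s2 / (4 * g^3) * common
    cqp <- s2 * k$kappa^2 / 2
    cpp <- s2 / (4 * g) * (1 + k$kappa * k$theta_prime - k$kappa_prime^2)
    C <- matrix(0, 6, 6)
    diag(C)[1:3] <- cqq
    diag(C)[4:6] <- cpp
    for (i in 1:3) C[i, i + 3] <- C[i + 3, i] <- cqp[i]
  } else {
    M <- jr_M(params)
    rhs <- function(t, y, parms) {
      C <- matrix(y, 6, 6)
      sig <- .sigma_at(input, t)
      SS <- matrix(0, 6, 6)
      diag(SS)[4:6] <- sig^2
      list(as.vector(M %*% C + C %*% t(M) + SS))
    }
    times <- seq(0, dt, length.out = substeps + 1)
    sol <- deSolve::ode(y = rep(0, 36), times = times, func = rhs,
                        parms = NULL, method = "rk4")
    C <- matrix(sol[nrow(sol), -1], 6, 6)
    C <- (C + t(C)) / 2
  }
  structure(C, dt = dt, method = method)
}

# symmetric PSD square root with small negative eigenvalues clipped at zero;
# errors when the matrix is materially non-PSD
.sym_sqrt <- function(C, tol = 1e-12) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- e$values
  scale <- max(abs(lam), 1e-300)
  if (any(lam < -tol * scale)) {
    stop("covariance matrix is not positive semidefinite")
  }
  lam[lam < 0] <- 0
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}
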