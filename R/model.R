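#' Sigmoid firing-rate gain
#'
#' Logistic map from mean membrane potential (mV) to mean population firing
#' rate (1/s), `nu_max / (1 + exp(r (v0 - x)))`. Strictly increasing and
#' bounded in (0, nu_max), with value `nu_max / 2` at `x = v0` and the
#' symmetry `Sigm(v0 + d) + Sigm(v0 - d) = nu_max`.
#'
#' @param x membrane potential(s), mV. Vectorised.
#' @param params a [jr_params()] object.
#' @return Firing rate(s), 1/s.
#' @examples
#' jr_sigmoid(6, jr_params())  # 2.5 at the half-activation potential
#' @export
jr_sigmoid <- function(x, params = jr_params()) {
  if (!all(is.finite(x))) stop("membrane potential must be finite")
  params$nu_max / (1 + exp(params$r * (params$v0 - x)))
}

# vectorised nonlinear displacement G^II(Q) for Q a 3 x n matrix
# rows of Q are (x0, x1, x2); returns a 3 x n matrix
.GII <- function(Q, params) {
  s <- function(x) params$nu_max / (1 + exp(params$r * (params$v0 - x)))
  rbind(params$A * params$a * s(Q[2, , drop = FALSE] - Q[3, , drop = FALSE]),
        params$A * params$a * params$C2 * s(params$C1 * Q[1, , drop = FALSE]),
        params$B * params$b * params$C4 * s(params$C3 * Q[1, , drop = FALSE]))
}

#' Nonlinear displacement G(t, Q)
#'
#' Evaluates the forcing of the momentum equation, split into its
#' time-dependent part `GI = (A a mu3(t), A a mu4(t), B b mu5(t))` and its
#' state-dependent part
#' `GII = (A a Sigm(x1 - x2), A a C2 Sigm(C1 x0), B b C4 Sigm(C3 x0))`.
#'
#' @param t time (s).
#' @param Q length-3 vector of mean postsynaptic potentials (x0, x1, x2), mV.
#' @param params a [jr_params()] object.
#' @param input a [jr_input()] object.
#' @return A list with components `GI`, `GII` and their sum `G` (length-3 each).
#' @export
jr_displacement <- function(t, Q, params = jr_params(), input = jr_input()) {
  stopifnot(length(Q) == 3, all(is.finite(Q)), is.finite(t))
  mu <- .mu_at(input, t)
  GI <- c(params$A * params$a * mu[1],
          params$A * params$a * mu[2],
          params$B * params$b * mu[3])
  GII <- as.numeric(.GII(matrix(Q, 3, 1), params))
  list(GI = GI, GII = GII, G = GI + GII)
}

#' Drift of the six-dimensional system
#'
#' The drift `f(t, X) = M X + (0, G(t, Q))` of the stochastic model: the first
#' three components equal `P`, the last three equal
#' `-Gamma^2 Q - 2 Gamma P + G(t, Q)`.
#'
#' @param t time (s).
#' @param x length-6 state `(x0, ..., x5) = (Q, P)`.
#' @param params a [jr_params()] object.
#' @param input a [jr_input()] object.
#' @return Length-6 numeric drift vector.
#' @export
jr_drift <- function(t, x, params = jr_params(), input = jr_input()) {
  stopifnot(length(x) == 6, all(is.finite(x)))
  g <- params$gamma
  Q <- x[1:3]; P <- x[4:6]
  G <- jr_displacement(t, Q, params, input)$G
  c(P, -g^2 * Q - 2 * g * P + G)
}

#' Hamiltonian energy and its rate of change
#'
#' `jr_hamiltonian` evaluates the total energy
#' `H(Q, P) = (||P||^2 + ||Gamma Q||^2) / 2` of the undamped oscillator part,
#' interpretable as the energy of an RCL parallel resonant circuit.
#' `jr_energy_rate` gives its time derivative along deterministic solutions,
#' `dH/dt = -2 P' Gamma P + P' G(t, Q)`.
#'
#' @param Q,P length-3 position (mV) and momentum (mV/s) vectors.
#' @param t time (s).
#' @param params a [jr_params()] object.
#' @param input a [jr_input()] object.
#' @return Scalar energy, respectively energy rate.
#' @export
jr_hamiltonian <- function(Q, P, params = jr_params()) {
  stopifnot(length(Q) == 3, length(P) == 3)
  g <- params$gamma
  (sum(P^2) + sum((g * Q)^2)) / 2
}

#' @rdname jr_hamiltonian
#' @export
jr_energy_rate <- function(t, Q, P, params = jr_params(), input = jr_input()) {
  g <- params$gamma
  G <- jr_displacement(t, Q, params, input)$G
  -2 * sum(P * g * P) + sum(P * G)
}

#' Closed-form kernel blocks of the linear flow
#'
#' The drift matrix `M` of the linear part is block-structured with diagonal
#' submatrices built from `Gamma = diag(a, a, b)`, so its matrix exponential
#' has the closed form
#' \deqn{e^{Mt} = \begin{pmatrix} \vartheta(t) & \kappa(t) \\
#'   \vartheta'(t) & \kappa'(t)\end{pmatrix}}
#' with `theta(t) = exp(-Gamma t)(I + Gamma t)`, `kappa(t) = exp(-Gamma t) t`,
#' `theta_prime(t) = -Gamma^2 exp(-Gamma t) t` and
#' `kappa_prime(t) = exp(-Gamma t)(I - Gamma t)`. All blocks are diagonal and
#' are returned as length-3 vectors of their diagonals. Negative `t` is
#' permitted and gives the inverse flow, `e^{-Mt} = (e^{Mt})^{-1}`.
#'
#' @param t time (s), scalar.
#' @param params a [jr_params()] object.
#' @return A list of class `jr_kernel_blocks` with elements `theta`, `kappa`,
#'   `theta_prime`, `kappa_prime` (length-3 diagonals), `Gamma` and `t`.
#' @seealso [jr_expM()] for the assembled 6 x 6 matrix.
#' @export
jr_kernel_blocks <- function(t, params = jr_params()) {
  stopifnot(is.finite(t), length(t) == 1)
  g <- params$gamma
  e <- exp(-g * t)
  out <- list(theta = e * (1 + g * t),
              kappa = e * t,
              theta_prime = -g^2 * e * t,
              kappa_prime = e * (1 - g * t),
              Gamma = g, t = t)
  class(out) <- "jr_kernel_blocks"
  out
}

#' Matrix exponential of the linear drift
#'
#' Assembles the 6 x 6 matrix `e^{M t}` from the diagonal kernel blocks.
#'
#' @inheritParams jr_kernel_blocks
#' @return A 6 x 6 numeric matrix.
#' @export
jr_expM <- function(t, params = jr_params()) {
  k <- jr_kernel_blocks(t, params)
  rbind(cbind(diag(k$theta), diag(k$kappa)),
        cbind(diag(k$theta_prime), diag(k$kappa_prime)))
}

#' Drift matrix of the linear part
#'
#' `M = [[0, I], [-Gamma^2, -2 Gamma]]` in block form.
#'
#' @param params a [jr_params()] object.
#' @return A 6 x 6 numeric matrix.
#' @export
jr_M <- function(params = jr_params()) {
  g <- params$gamma
  rbind(cbind(matrix(0, 3, 3), diag(3)),
        cbind(diag(-g^2), diag(-2 * g)))
}

#' Lyapunov functional of the damped system
#'
#' Evaluates
#' `V_n(Q, P) = (1 + ||P||^2 / 2 + 3 ||Gamma Q||^2 / 2 + <P, Gamma Q>)^n`.
#' For `a, b > 0` the quadratic form inside the parenthesis is positive
#' definite (its matrix has eigenvalues bounded below by (2 - sqrt(2))/2 > 1/4
#' per conjugate pair), so `V_n >= 1` everywhere and `V_n` is radially
#' unbounded; it certifies existence of invariant measures and, with fully
#' elliptic noise, geometric ergodicity.
#'
#' @param Q,P length-3 position and momentum vectors, or 3 x n matrices
#'   (evaluated columnwise).
#' @param params a [jr_params()] object.
#' @param n positive integer power.
#' @return Scalar (or length-n vector for matrix input).
#' @export
jr_lyapunov <- function(Q, P, params = jr_params(), n = 1) {
  if (!(is.numeric(n) && length(n) == 1 && n >= 1 && n == round(n))) {
    stop("n must be a positive integer")
  }
  if (is.matrix(Q) || is.matrix(P)) {
    Q <- as.matrix(Q); P <- as.matrix(P)
    stopifnot(nrow(Q) == 3, nrow(P) == 3, ncol(Q) == ncol(P))
    g <- params$gamma
    gQ <- g * Q
    base <- 1 + colSums(P^2) / 2 + 1.5 * colSums(gQ^2) + colSums(P * gQ)
    return(base^n)
  }
  stopifnot(length(Q) == 3, length(P) == 3)
  g <- params$gamma
  gQ <- g * Q
  (1 + sum(P^2) / 2 + 1.5 * sum(gQ^2) + sum(P * gQ))^n
}
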