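#' Simulate a trajectory of the stochastic Jansen-Rit model
#'
#' Advances the six-dimensional state from `x0` over `[0, t_end]` on an
#' equidistant grid with the chosen one-step map and returns the trajectory as
#' a tibble with the state columns `x0 .. x5` (ordering `(Q, P)`) and the
#' output signal `y = x1 - x2`, the average membrane potential of the
#' principal cells. Runs are reproducible: the same `seed` yields bit-identical
#' trajectories.
#'
#' @param params a [jr_params()] object.
#' @param input a [jr_input()] object.
#' @param x0 length-6 initial state.
#' @param t_end time horizon (s).
#' @param dt step size (s); `t_end / dt` must be integral within rounding.
#' @param scheme one of `"strang"`, `"ou"`, `"wiener"`, `"em"`.
#' @param seed integer seed for the noise draws, or `NULL` to use the current
#'   RNG state.
#' @param keep_noise record the applied Gaussian momentum increments
#'   `Sigma dW` per step (schemes `"wiener"`, `"strang"`, `"em"`), needed by
#'   [convolution_reconstruct()].
#' @param commute reverse the Lie-Trotter composition order (see [jr_step()]).
#' @return A tibble of class `jr_trajectory` with columns
#'   `t, x0, ..., x5, y` and attributes `scheme`, `dt`, `seed`, `params`,
#'   `input`, `x0_init` and (optionally) `noise`.
#' @examples
#' sc <- jr_preset("alpha_C135")
#' tr <- jr_simulate(sc$params, sc$input, t_end = 1, dt = 1e-3, seed = 1)
#' head(tr)
#' @export
jr_simulate <- function(params = jr_params(), input = jr_input(),
                        x0 = rep(0, 6), t_end = 10, dt = 1e-3,
                        scheme = "strang", seed = NULL,
                        keep_noise = FALSE, commute = FALSE) {
  stopifnot(t_end > 0, dt > 0, length(x0) == 6, all(is.finite(x0)))
  N <- round(t_end / dt)
  if (abs(N * dt - t_end) > 1e-8 * max(t_end, 1)) {
    stop("t_end must be an integer multiple of dt")
  }
  if (!is.null(seed)) set.seed(seed)
  ctx <- .ctx_new(params, input, dt, scheme, commute)
  stepf <- .step_fun(ctx$scheme)
  d <- .draw_dim(ctx$scheme)

  states <- matrix(NA_real_, N + 1, 6)
  states[1, ] <- x0
  noise <- if (keep_noise && ctx$scheme != "ou") matrix(NA_real_, 3, N) else NULL
  X <- matrix(x0, 6, 1)
  tgrid <- (0:N) * dt
  for (i in seq_len(N)) {
    t_i <- tgrid[i]
    inc <- .scale_draws(ctx, t_i, .std_draws(d, 1))
    if (!is.null(noise)) noise[, i] <- inc
    X <- stepf(ctx, X, t_i, inc)
    if (!all(is.finite(X))) {
      stop(sprintf("non-finite state encountered at step %d (t = %g s)", i, tgrid[i + 1]))
    }
    states[i + 1, ] <- X
  }

  out <- tibble::tibble(t = tgrid,
                        x0 = states[, 1], x1 = states[, 2], x2 = states[, 3],
                        x3 = states[, 4], x4 = states[, 5], x5 = states[, 6],
                        y = states[, 2] - states[, 3])
  class(out) <- c("jr_trajectory", class(out))
  attr(out, "scheme") <- ctx$scheme
  attr(out, "dt") <- dt
  attr(out, "seed") <- seed
  attr(out, "params") <- params
  attr(out, "input") <- input
  attr(out, "x0_init") <- x0
  attr(out, "commute") <- commute
  if (!is.null(noise)) attr(out, "noise") <- noise
  out
}

#' Monte-Carlo ensemble of trajectories
#'
#' Advances `n_paths` independent paths simultaneously (the steppers are
#' vectorised over paths) and records the full state at the requested grid
#' times only, keeping memory proportional to the number of recorded nodes.
#'
#' @inheritParams jr_simulate
#' @param n_paths number of independent paths.
#' @param record_times times at which to record states; must lie on the step
#'   grid (within rounding). Default: ten equally spaced times up to `t_end`.
#' @return A list of class `jr_ensemble` with elements `times` (length m),
#'   `states` (array 6 x n_paths x m), `scheme`, `dt`, `seed`.
#' @export
jr_ensemble <- function(params = jr_params(), input = jr_input(),
                        x0 = rep(0, 6), t_end = 1, dt = 1e-3,
                        scheme = "strang", n_paths = 1000, seed = NULL,
                        record_times = NULL, commute = FALSE) {
  stopifnot(t_end > 0, dt > 0, n_paths >= 1)
  N <- round(t_end / dt)
  if (abs(N * dt - t_end) > 1e-8 * max(t_end, 1)) {
    stop("t_end must be an integer multiple of dt")
  }
  if (is.null(record_times)) record_times <- seq(t_end / 10, t_end, length.out = 10)
  rec_idx <- round(record_times / dt)
  if (any(abs(rec_idx * dt - record_times) > 1e-8 * max(t_end, 1))) {
    stop("record_times must lie on the step grid")
  }
  if (!is.null(seed)) set.seed(seed)
  ctx <- .ctx_new(params, input, dt, scheme, commute)
  stepf <- .step_fun(ctx$scheme)
  d <- .draw_dim(ctx$scheme)

  X <- matrix(x0, 6, n_paths)
  states <- array(NA_real_, c(6, n_paths, length(rec_idx)))
  hit <- match(0:N, rec_idx)
  if (!is.na(hit[1])) states[, , hit[1]] <- X
  for (i in seq_len(N)) {
    t_i <- (i - 1) * dt
    X <- stepf(ctx, X, t_i, .scale_draws(ctx, t_i, .std_draws(d, n_paths)))
    if (!is.na(hit[i + 1])) states[, , hit[i + 1]] <- X
  }
  structure(list(times = rec_idx * dt, states = states, scheme = ctx$scheme,
                 dt = dt, seed = seed, n_paths = n_paths),
            class = "jr_ensemble")
}

#' @export
print.jr_ensemble <- function(x, ...) {
  cat(sprintf("<jr_ensemble> %d paths, scheme %s, dt = %g s, %d recorded times\n",
              x$n_paths, x$scheme, x$dt, length(x$times)))
  invisible(x)
}

#' @export
print.jr_trajectory <- function(x, ...) {
  cat(sprintf("<jr_trajectory> scheme %s, dt = %g s, %d nodes\n",
              attr(x, "scheme"), attr(x, "dt"), nrow(x)))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulated trajectory into long form
#'
#' @param x a `jr_trajectory`.
#' @param ... unused.
#' @return A tibble with columns `t`, `variable`, `value`.
#' @method tidy jr_trajectory
#' @export
tidy.jr_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"t",
                      names_to = "variable", values_to = "value")
}

#' One-row summary of a simulated trajectory
#'
#' @param x a `jr_trajectory`.
#' @param ... unused.
#' @return A one-row tibble with the scheme, grid and output-signal summary.
#' @method glance jr_trajectory
#' @export
glance.jr_trajectory <- function(x, ...) {
  tibble::tibble(scheme = attr(x, "scheme"), dt = attr(x, "dt"),
                 t_end = max(x$t), n_steps = nrow(x) - 1L,
                 seed = if (is.null(attr(x, "seed"))) NA_integer_ else attr(x, "seed"),
                 y_mean = mean(x$y), y_sd = stats::sd(x$y))
}

#' Plot the output signal of a trajectory
#'
#' @param object a `jr_trajectory`.
#' @param ... unused.
#' @return A ggplot object: `y(t)` against time.
#' @method autoplot jr_trajectory
#' @export
autoplot.jr_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "output signal y = x1 - x2 (mV)",
                  title = sprintf("scheme: %s, dt = %g s",
                                  attr(object, "scheme"), attr(object, "dt")))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
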