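# Mean-square convergence-order estimation.
#
# All schemes at all step-sizes are driven by one shared Brownian path per
# Monte-Carlo replicate: raw increments are generated on the reference grid
# (step dt_ref = min(dt)/ref_refine) and aggregated to each coarser grid, so
# coarse increments are exact sums of fine ones. The reference solution is the
# Strang splitting on the fine grid (no closed-form solution exists). For the
# Ornstein-Uhlenbeck splitting the exact Gaussian increment
# xi = int e^{M(dt - s)} S dW(s) is reconstructed from the fine increments by
# a left-point rectangle rule, whose mean-square error is O(dt_ref) - the same
# order as the reference itself.

# aggregate fine raw increments (N_ref x n) to a coarser grid by summation
.aggregate_increments <- function(W, ratio) {
  if (ratio == 1) return(W)
  n_coarse <- nrow(W) / ratio
  rowsum(W, rep(seq_len(n_coarse), each = ratio))
}

# OU increments xi (6 x n x N_coarse) from fine raw increments, left-point rule
.ou_xi_from_fine <- function(W, dt, dt_ref, sig, g) {
  r <- round(dt / dt_ref)
  n <- ncol(W[[1]])
  n_coarse <- nrow(W[[1]]) / r
  xi <- array(0, c(6, n, n_coarse))
  s_left <- (0:(r - 1)) * dt_ref
  arg <- dt - s_left                      # kappa arguments, length r
  for (c in 1:3) {
    e <- exp(-g[c] * arg)
    wQ <- sig[c] * e * arg                # kappa_c(dt - s_j)
    wP <- sig[c] * e * (1 - g[c] * arg)   # kappa'_c(dt - s_j)
    Wmat <- matrix(W[[c]], nrow = r)      # r x (n_coarse * n), steps fastest
    xi[c, , ] <- t(matrix(as.numeric(wQ %*% Wmat), n_coarse, n))
    xi[c + 3, , ] <- t(matrix(as.numeric(wP %*% Wmat), n_coarse, n))
  }
  xi
}

# advance all paths with externally supplied increments; returns final states
.run_coupled <- function(scheme, params, input, x0, dt, Wc, xi = NULL,
                         commute = FALSE) {
  ctx <- .ctx_new(params, input, dt, scheme, commute, need_cov = FALSE)
  stepf <- .step_fun(scheme)
  sig <- .sigma_const(input)
  n <- ncol(Wc[[1]])
  N <- nrow(Wc[[1]])
  X <- matrix(x0, 6, n)
  for (i in seq_len(N)) {
    inc <- if (scheme == "ou") {
      xi[, , i, drop = FALSE][, , 1]
    } else {
      rbind(sig[1] * Wc[[1]][i, ], sig[2] * Wc[[2]][i, ], sig[3] * Wc[[3]][i, ])
    }
    if (n == 1) inc <- matrix(inc, nrow = if (scheme == "ou") 6 else 3)
    X <- stepf(ctx, X, (i - 1) * dt, inc)
  }
  X
}

#' Estimate the mean-square convergence order of a scheme
#'
#' Runs `n_paths` coupled Monte-Carlo replicates of the chosen scheme at each
#' step-size in `dt` against a fine-step Strang reference driven by the same
#' Brownian paths (coarse increments are exact sums of the fine-grid
#' increments), measures the root-mean-square endpoint error, and fits the
#' log-log slope. The splitting schemes and Euler-Maruyama are mean-square
#' order one for this additive-noise system; with the noise switched off the
#' Strang map is a deterministic second-order method while the Lie-Trotter
#' maps are first order.
#'
#' @param scheme scheme under study: `"strang"`, `"ou"`, `"wiener"` or `"em"`.
#' @param params a [jr_params()] object.
#' @param input a [jr_input()] object; the diffusion matrix must be constant.
#' @param t_end time horizon (s).
#' @param dt strictly decreasing vector (length >= 3) of dyadic refinements of
#'   the coarsest step.
#' @param n_paths Monte-Carlo replicates.
#' @param seed integer seed.
#' @param x0 length-6 initial state.
#' @param ref_refine the reference grid is `min(dt) / ref_refine`.
#' @param n_groups path groups used for the replicate-based slope standard error.
#' @return An object of class `jr_convergence`: a list with a tibble `errors`
#'   (`dt`, `rmse`), the fitted `slope`, its replicate-based `slope_se`, and
#'   the run metadata.
#' @examples
#' \donttest{
#' rep <- estimate_ms_order("strang", jr_params(), jr_input(sigma = c(0, 0, 0)),
#'                          t_end = 0.5, n_paths = 1, seed = 1)
#' glance(rep)
#' }
#' @export
estimate_ms_order <- function(scheme, params = jr_params(), input = jr_input(),
                              t_end = 1, dt = c(4e-3, 2e-3, 1e-3, 5e-4),
                              n_paths = 500, seed = NULL, x0 = rep(0, 6),
                              ref_refine = 4, n_groups = 5) {
  scheme <- match.arg(scheme, .schemes)
  if (length(dt) < 3) stop("at least 3 step-sizes are required")
  if (any(diff(dt) >= 0)) stop("step-sizes must be strictly decreasing")
  ratios <- dt[1] / dt
  if (any(abs(ratios - 2^round(log2(ratios))) > 1e-10)) {
    stop("step-sizes must be dyadic refinements of the coarsest step")
  }
  if (!input_has_constant_sigma(input)) {
    stop("convergence studies require a constant diffusion matrix")
  }
  dt_ref <- min(dt) / ref_refine
  N_ref <- round(t_end / dt_ref)
  steps <- t_end / c(dt, dt_ref)
  if (any(abs(steps - round(steps)) > 1e-8 * steps)) {
    stop("t_end must be an integer multiple of every step-size")
  }
  if (!is.null(seed)) set.seed(seed)
  sig <- .sigma_const(input)

  W <- lapply(1:3, function(c) {
    matrix(stats::rnorm(N_ref * n_paths, sd = sqrt(dt_ref)), N_ref, n_paths)
  })

  X_ref <- .run_coupled("strang", params, input, x0, dt_ref, W)

  sq_err <- matrix(NA_real_, n_paths, length(dt))  # per-path squared errors
  for (j in seq_along(dt)) {
    r <- round(dt[j] / dt_ref)
    Wc <- lapply(W, .aggregate_increments, ratio = r)
    xi <- if (scheme == "ou") .ou_xi_from_fine(W, dt[j], dt_ref, sig, params$gamma)
    X_j <- .run_coupled(scheme, params, input, x0, dt[j], Wc, xi)
    sq_err[, j] <- colSums((X_j - X_ref)^2)
  }
  rmse <- sqrt(colMeans(sq_err))
  fit <- stats::lm(log(rmse) ~ log(dt))
  slope <- unname(stats::coef(fit)[2])

  # replicate-based slope uncertainty: slope per path group
  slope_se <- NA_real_
  if (n_paths >= n_groups && n_groups >= 2) {
    grp <- rep(seq_len(n_groups), length.out = n_paths)
    slopes <- vapply(seq_len(n_groups), function(gi) {
      rg <- sqrt(colMeans(sq_err[grp == gi, , drop = FALSE]))
      unname(stats::coef(stats::lm(log(rg) ~ log(dt)))[2])
    }, numeric(1))
    slope_se <- stats::sd(slopes) / sqrt(n_groups)
  }

  structure(list(errors = tibble::tibble(dt = dt, rmse = rmse),
                 slope = slope, slope_se = slope_se,
                 scheme = scheme, n_paths = n_paths, t_end = t_end,
                 dt_ref = dt_ref, seed = seed),
            class = "jr_convergence")
}

#' @export
print.jr_convergence <- function(x, ...) {
  cat(sprintf("<jr_convergence> scheme %s, %d paths, T = %g s\n",
              x$scheme, x$n_paths, x$t_end))
  cat(sprintf("  fitted mean-square order: %.3f (SE %.3f)\n", x$slope, x$slope_se))
  print(x$errors)
  invisible(x)
}

#' Tidy the step-size/error table of a convergence report
#' @param x a `jr_convergence` object.
#' @param ... unused.
#' @return A tibble with columns `dt` and `rmse`.
#' @method tidy jr_convergence
#' @export
tidy.jr_convergence <- function(x, ...) x$errors

#' One-row summary of a convergence report
#' @param x a `jr_convergence` object.
#' @param ... unused.
#' @return A one-row tibble with scheme, fitted slope and its standard error.
#' @method glance jr_convergence
#' @export
glance.jr_convergence <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, slope = x$slope, slope_se = x$slope_se,
                 n_paths = x$n_paths, t_end = x$t_end, dt_ref = x$dt_ref)
}

#' Log-log plot of RMS endpoint error against step-size
#' @param object a `jr_convergence` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot jr_convergence
#' @export
autoplot.jr_convergence <- function(object, ...) {
  ggplot2::ggplot(object$errors, ggplot2::aes(x = .data$dt, y = .data$rmse)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "step size (s)", y = "RMS endpoint error",
                  title = sprintf("%s splitting: fitted order %.2f",
                                  object$scheme, object$slope))
}
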