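# Long-run simulation, invariant-measure density estimation of the output
# signal, ergodic time averaging, and the empirical discrete Lyapunov drift
# check. With all three noise scales strictly positive the model has a unique
# invariant measure and is geometrically ergodic, so long single-path runs
# estimate stationary quantities irrespective of the initial state.

#' Long-run sample of the stationary regime
#'
#' Simulates a single long path, discards a burn-in, and subsamples the
#' remainder with a fixed stride. The samples approximate draws from the
#' invariant measure when the noise is fully elliptic (all `sigma_i > 0`
#' constants); otherwise uniqueness of the invariant measure is not
#' guaranteed and a warning is issued.
#'
#' @inheritParams jr_simulate
#' @param burn_in initial time span to discard (s); must be `< t_end`.
#' @param stride keep every `stride`-th post-burn-in node.
#' @return A tibble with columns `t, x0, ..., x5, y` (the retained samples)
#'   and attributes `n_effective`, `burn_in`, `stride`, `dt`, `scheme`.
#' @examples
#' \donttest{
#' sc <- jr_preset("alpha_C135")
#' lr <- long_run(sc$params, sc$input, t_end = 40, burn_in = 10, seed = 1)
#' }
#' @export
long_run <- function(params = jr_params(), input = jr_input(),
                     t_end = 200, dt = 1e-3, burn_in = 10, stride = 10,
                     scheme = "strang", seed = NULL, x0 = rep(0, 6)) {
  stopifnot(burn_in >= 0, burn_in < t_end, stride >= 1)
  if (!input_is_elliptic(input)) {
    warning("some noise scales are zero or time-dependent: ",
            "uniqueness of the invariant measure is not guaranteed")
  }
  tr <- jr_simulate(params, input, x0, t_end, dt, scheme, seed)
  keep <- tr$t >= burn_in
  idx <- which(keep)
  idx <- idx[seq(1, length(idx), by = stride)]
  out <- tr[idx, ]
  class(out) <- setdiff(class(out), "jr_trajectory")
  attr(out, "n_effective") <- length(idx)
  attr(out, "burn_in") <- burn_in
  attr(out, "stride") <- stride
  attr(out, "dt") <- dt
  attr(out, "scheme") <- scheme
  out
}

#' Gaussian kernel density estimate on a grid
#'
#' Plain Gaussian-kernel estimator evaluated on an explicit grid (so that
#' densities from different runs can be compared pointwise). The default
#' bandwidth is Silverman's rule of thumb ([stats::bw.nrd0()]); samples with
#' zero variance require an explicit bandwidth. The number of modes is
#' recorded as the count of local maxima exceeding 5% of the global maximum
#' whose separating valleys drop below 80% of the smaller neighbouring peak
#' (a prominence requirement: shallow double bumps count as one mode).
#'
#' @param samples numeric vector of at least 100 observations (typically the
#'   output signal `y` from [long_run()]).
#' @param grid evaluation grid; default 512 points spanning the sample range
#'   extended by three bandwidths.
#' @param bandwidth kernel standard deviation; default Silverman's rule.
#' @return A tibble of class `jr_density` with columns `y`, `density` and
#'   attributes `bandwidth`, `n`, `modality`.
#' @export
kde_density <- function(samples, grid = NULL, bandwidth = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 100) stop("at least 100 samples are required")
  if (is.null(bandwidth)) {
    if (stats::sd(samples) == 0) {
      stop("samples have zero variance; supply a bandwidth explicitly")
    }
    bandwidth <- stats::bw.nrd0(samples)
  }
  stopifnot(bandwidth > 0)
  if (is.null(grid)) {
    grid <- seq(min(samples) - 3 * bandwidth, max(samples) + 3 * bandwidth,
                length.out = 512)
  }
  dens <- vapply(grid, function(g) {
    mean(stats::dnorm(g, mean = samples, sd = bandwidth))
  }, numeric(1))
  out <- tibble::tibble(y = grid, density = dens)
  class(out) <- c("jr_density", class(out))
  attr(out, "bandwidth") <- bandwidth
  attr(out, "n") <- length(samples)
  attr(out, "modality") <- .count_modes(dens)
  out
}

# modes = local maxima above rel_height of the global maximum that are also
# prominent: the valley between two neighbouring counted peaks must drop below
# (1 - min_prominence) of the smaller peak, otherwise the pair is one mode
# (shallow double bumps from the oscillation's turning points do not count)
.count_modes <- function(dens, rel_height = 0.05, min_prominence = 0.2) {
  n <- length(dens)
  if (n < 3) return(as.integer(any(dens > 0)))
  thr <- rel_height * max(dens)
  peaks <- which(dens[2:(n - 1)] > dens[1:(n - 2)] &
                   dens[2:(n - 1)] >= dens[3:n]) + 1L
  peaks <- peaks[dens[peaks] > thr]
  while (length(peaks) > 1) {
    ratio <- vapply(seq_len(length(peaks) - 1), function(j) {
      valley <- min(dens[peaks[j]:peaks[j + 1]])
      valley / min(dens[peaks[j]], dens[peaks[j + 1]])
    }, numeric(1))
    worst <- which.max(ratio)
    if (ratio[worst] <= 1 - min_prominence) break
    drop <- if (dens[peaks[worst]] < dens[peaks[worst + 1]]) worst else worst + 1
    peaks <- peaks[-drop]
  }
  length(peaks)
}

#' Number of modes of a density estimate
#' @param density a `jr_density` object.
#' @return Integer count of prominent local maxima (above 5% of the global
#'   maximum, with the valley between counted peaks below 80% of the smaller).
#' @export
modality <- function(density) {
  stopifnot(inherits(density, "jr_density"))
  attr(density, "modality")
}

#' L1 distance between two density estimates on a common grid
#' @param d1,d2 `jr_density` objects evaluated on the same grid.
#' @return Scalar trapezoidal approximation of `int |f1 - f2|`.
#' @export
density_l1 <- function(d1, d2) {
  stopifnot(inherits(d1, "jr_density"), inherits(d2, "jr_density"),
            isTRUE(all.equal(d1$y, d2$y)))
  .trapz(d1$y, abs(d1$density - d2$density))
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' @export
print.jr_density <- function(x, ...) {
  cat(sprintf("<jr_density> n = %d, bandwidth = %.4g, %d mode(s)\n",
              attr(x, "n"), attr(x, "bandwidth"), attr(x, "modality")))
  NextMethod()
}

#' @rdname kde_density
#' @param x a `jr_density` object.
#' @param ... unused.
#' @method tidy jr_density
#' @export
tidy.jr_density <- function(x, ...) tibble::as_tibble(x)

#' @rdname kde_density
#' @method glance jr_density
#' @export
glance.jr_density <- function(x, ...) {
  tibble::tibble(bandwidth = attr(x, "bandwidth"), n = attr(x, "n"),
                 modality = attr(x, "modality"),
                 mass = .trapz(x$y, x$density))
}

#' Plot an estimated invariant density of the output signal
#' @param object a `jr_density` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot jr_density
#' @export
autoplot.jr_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$y, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "output signal y (mV)", y = "density",
                  title = sprintf("invariant-density estimate (%d mode(s))",
                                  attr(object, "modality")))
}

#' Ergodic time average with batch-means standard error
#'
#' Estimates `E[h(X)]` under the invariant measure as the time average of `h`
#' over long-run samples, with a batch-means standard error (the samples are
#' autocorrelated, so the naive iid standard error would be too small).
#'
#' @param samples a tibble of long-run samples (from [long_run()]).
#' @param h a function of the samples tibble returning one numeric value per
#'   row, e.g. `function(s) s$x1` or `function(s) s$x1^2`.
#' @param n_batches number of equal-length batches.
#' @return A one-row tibble with `estimate`, `se`, `n`, `n_batches`.
#' @export
time_average <- function(samples, h, n_batches = 30) {
  v <- h(samples)
  stopifnot(is.numeric(v), length(v) == nrow(samples))
  n <- length(v)
  nb <- min(n_batches, n)
  batch <- rep(seq_len(nb), each = ceiling(n / nb))[seq_len(n)]
  bm <- tapply(v, batch, mean)
  se <- if (nb > 1) stats::sd(bm) / sqrt(nb) else 0
  if (stats::sd(v) == 0) se <- 0
  tibble::tibble(estimate = mean(v), se = se, n = n, n_batches = nb)
}

#' Empirical discrete Lyapunov drift check
#'
#' Verifies the one-step contraction of the Lyapunov functional `V_1` along a
#' simulated chain: transitions are binned into `n_bins` equal-count bins of
#' `V_1(X_i)` and the bin means of `V_1(X_{i+1})` are regressed on the bin
#' means of `V_1(X_i)`. A fitted slope below one is the empirical counterpart
#' of the discrete drift condition
#' `E[V(X_{i+1}) | X_i] <= alpha V(X_i) + beta` with `alpha < 1`, which holds
#' for the splitting schemes whenever `dt < 1 / (2 max(a, b))`. When `dt`
#' violates that restriction the report flags it and no contraction is
#' asserted.
#'
#' @inheritParams jr_simulate
#' @param n_transitions number of one-step transitions (>= 1e4).
#' @param n_bins number of equal-count bins.
#' @return An object of class `jr_drift_check`: list with `slope`,
#'   `intercept`, `dt`, `dt_max`, `hypothesis_ok`, `contractive`,
#'   `n_transitions` and the binned means tibble `bins`.
#' @export
drift_check <- function(params = jr_params(), input = jr_input(),
                        dt = 1e-3, n_transitions = 2e4, scheme = "wiener",
                        seed = NULL, x0 = rep(0, 6), n_bins = 20) {
  if (n_transitions < 1e4) stop("at least 1e4 transitions are required")
  dt_max <- 1 / (2 * max(params$a, params$b))
  hypothesis_ok <- dt < dt_max
  tr <- jr_simulate(params, input, x0, t_end = n_transitions * dt, dt = dt,
                    scheme = scheme, seed = seed)
  S <- as.matrix(tr[, c("x0", "x1", "x2", "x3", "x4", "x5")])
  V <- jr_lyapunov(t(S[, 1:3]), t(S[, 4:6]), params)
  vi <- V[-length(V)]
  vnext <- V[-1]
  qs <- stats::quantile(vi, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(vi, breaks = unique(qs), include.lowest = TRUE)
  bins <- tibble::tibble(v = as.numeric(tapply(vi, bin, mean)),
                         v_next = as.numeric(tapply(vnext, bin, mean)))
  fit <- stats::lm(v_next ~ v, data = bins)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(list(slope = slope, intercept = intercept, dt = dt,
                 dt_max = dt_max, hypothesis_ok = hypothesis_ok,
                 contractive = hypothesis_ok && slope < 1,
                 n_transitions = n_transitions, scheme = scheme, bins = bins),
            class = "jr_drift_check")
}

#' @export
print.jr_drift_check <- function(x, ...) {
  cat(sprintf("<jr_drift_check> scheme %s, dt = %g s (restriction dt < %g: %s)\n",
              x$scheme, x$dt, x$dt_max,
              if (x$hypothesis_ok) "satisfied" else "VIOLATED"))
  cat(sprintf("  fitted one-step V1 regression: slope %.4f, intercept %.4g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' @rdname drift_check
#' @param x a `jr_drift_check` object.
#' @param ... unused.
#' @method tidy jr_drift_check
#' @export
tidy.jr_drift_check <- function(x, ...) x$bins

#' @rdname drift_check
#' @method glance jr_drift_check
#' @export
glance.jr_drift_check <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, dt = x$dt,
                 dt_max = x$dt_max, hypothesis_ok = x$hypothesis_ok,
                 contractive = x$contractive, n_transitions = x$n_transitions)
}
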