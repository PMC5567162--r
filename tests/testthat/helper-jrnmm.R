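# shared fixtures: the classical parameter set, the alpha-rhythm drive, and
# degenerate variants used to isolate the linear / deterministic sub-dynamics

p_tab1 <- jr_params()                                  # C = 135, Table-typical values
input_alpha <- jr_input()                              # mu = (0,220,0), sigma = (10,1000,10)
input_det <- jr_input(sigma = c(0, 0, 0))              # same drive, no noise
p_linear <- jr_params(nu_max = 0)                      # sigmoid switched off
input_zero <- jr_input(mu = c(0, 0, 0), sigma = c(0, 0, 0))

rand_states <- function(n, scale = c(10, 10, 10, 500, 500, 500), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(6 * n, sd = scale), 6, n)
}

expect_rel_equal <- function(object, expected, tol) {
  denom <- max(abs(expected), .Machine$double.eps)
  expect_lt(max(abs(object - expected)) / denom, tol)
}
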