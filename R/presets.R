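# Scenario presets matching the classical simulation regimes: the
# alpha-rhythm drive mu = (0, 220, 0) with noise sigma = (10, 1000, 10) for
# coupling constants C in {68, 135, 270, 675}, and a small-noise variant
# sigma = (1, 200, 1) from zero initial state used for phase-portrait studies.

.preset_names <- c("alpha_C68", "alpha_C135", "alpha_C270", "alpha_C675",
                   "phase_C135_smallnoise")

#' Scenario presets
#'
#' Returns a complete simulation scenario (parameters, inputs, initial state,
#' horizon, step-size, scheme) for the named regime. The `alpha_C*` presets
#' use the alpha-rhythm drive `mu = (0, 220, 0)` with noise
#' `sigma = (10, 1000, 10)` and differ only in the average synapse number `C`;
#' `phase_C135_smallnoise` uses `sigma = (1, 200, 1)` from the zero state.
#' All presets start at `X(0) = 0` (geometric ergodicity makes the long-run
#' behaviour insensitive to this choice).
#'
#' @param name one of `"alpha_C68"`, `"alpha_C135"`, `"alpha_C270"`,
#'   `"alpha_C675"`, `"phase_C135_smallnoise"`.
#' @return An object of class `jr_scenario`: a list with elements `name`,
#'   `params`, `input`, `x0`, `t_end`, `dt`, `scheme`.
#' @examples
#' sc <- jr_preset("alpha_C135")
#' sc$params$C
#' @export
jr_preset <- function(name) {
  if (!is.character(name) || length(name) != 1 || !(name %in% .preset_names)) {
    stop(sprintf("unknown preset %s; available: %s",
                 deparse(substitute(name)), paste(.preset_names, collapse = ", ")))
  }
  spec <- switch(name,
    alpha_C68  = list(C = 68,  sigma = c(10, 1000, 10)),
    alpha_C135 = list(C = 135, sigma = c(10, 1000, 10)),
    alpha_C270 = list(C = 270, sigma = c(10, 1000, 10)),
    alpha_C675 = list(C = 675, sigma = c(10, 1000, 10)),
    phase_C135_smallnoise = list(C = 135, sigma = c(1, 200, 1)))
  structure(list(name = name,
                 params = jr_params(C = spec$C),
                 input = jr_input(mu = c(0, 220, 0), sigma = spec$sigma),
                 x0 = rep(0, 6), t_end = 10, dt = 1e-3, scheme = "strang"),
            class = "jr_scenario")
}

#' @export
print.jr_scenario <- function(x, ...) {
  cat(sprintf("<jr_scenario> %s: C = %g, T = %g s, dt = %g s, scheme %s\n",
              x$name, x$params$C, x$t_end, x$dt, x$scheme))
  invisible(x)
}

#' List the available scenario presets
#' @return Character vector of preset names.
#' @export
jr_presets <- function() .preset_names

#' Write a scenario to a flat key=value config file
#'
#' Serialises a scenario with constant inputs to a plain-text file, one
#' `key=value` pair per line. Keys: `name`, the model constants (`A`, `B`,
#' `a`, `b`, `C`, `C1..C4`, `nu_max`, `v0`, `r`), the inputs (`mu3..mu5`,
#' `sigma3..sigma5`), the initial state (`x0_0..x0_5`), and `t_end`, `dt`,
#' `scheme`. [jr_read_config()] reproduces the scenario exactly.
#'
#' @param scenario a `jr_scenario` (or a list with the same elements).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
jr_write_config <- function(scenario, path) {
  p <- scenario$params
  inp <- scenario$input
  if (!all(inp$mu_const) || !all(inp$sigma_const)) {
    stop("only scenarios with constant inputs can be serialised")
  }
  kv <- c(name = scenario$name,
          A = p$A, B = p$B, a = p$a, b = p$b, C = p$C,
          C1 = p$C1, C2 = p$C2, C3 = p$C3, C4 = p$C4,
          nu_max = p$nu_max, v0 = p$v0, r = p$r,
          mu3 = inp$mu[[1]], mu4 = inp$mu[[2]], mu5 = inp$mu[[3]],
          sigma3 = inp$sigma[[1]], sigma4 = inp$sigma[[2]],
          sigma5 = inp$sigma[[3]],
          stats::setNames(scenario$x0, paste0("x0_", 0:5)),
          t_end = scenario$t_end, dt = scenario$dt, scheme = scenario$scheme)
  writeLines(paste0(names(kv), "=",
                    vapply(kv, function(v) format(v, digits = 17), character(1))),
             path)
  invisible(path)
}

#' Read a scenario from a flat key=value config file
#' @param path path to a file written by [jr_write_config()].
#' @return A `jr_scenario` object.
#' @export
jr_read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  kv <- stats::setNames(vapply(parts, function(x) paste(x[-1], collapse = "="),
                               character(1)),
                        vapply(parts, `[[`, character(1), 1))
  num <- function(key) {
    if (!key %in% names(kv)) stop(sprintf("config is missing key '%s'", key))
    as.numeric(kv[[key]])
  }
  params <- jr_params(C = num("C"), A = num("A"), B = num("B"),
                      a = num("a"), b = num("b"),
                      C1 = num("C1"), C2 = num("C2"),
                      C3 = num("C3"), C4 = num("C4"),
                      nu_max = num("nu_max"), v0 = num("v0"), r = num("r"))
  input <- jr_input(mu = c(num("mu3"), num("mu4"), num("mu5")),
                    sigma = c(num("sigma3"), num("sigma4"), num("sigma5")))
  structure(list(name = unname(kv[["name"]]), params = params, input = input,
                 x0 = vapply(paste0("x0_", 0:5), num, numeric(1),
                             USE.NAMES = FALSE),
                 t_end = num("t_end"), dt = num("dt"),
                 scheme = match.arg(kv[["scheme"]], .schemes)),
            class = "jr_scenario")
}
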