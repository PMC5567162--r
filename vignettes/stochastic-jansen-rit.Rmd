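---
title: "Methods: the stochastic Jansen–Rit model and its splitting integrators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the stochastic Jansen-Rit model and its splitting integrators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

The Jansen–Rit neural mass model describes a cortical column by the mean
postsynaptic potentials of three interacting populations — pyramidal cells,
excitatory and inhibitory interneurons. Writing positions
`Q = (x0, x1, x2)` (mV) and momenta `P = (x3, x4, x5)` (mV/s), the
stochastic model treated here is the damped Hamiltonian system with nonlinear
displacement

    dQ = ∇_P H(Q, P) dt
    dP = (−∇_Q H(Q, P) − 2ΓP + G(t, Q)) dt + Σ dW,

with `H(Q, P) = (‖P‖² + ‖ΓQ‖²)/2`, damping `Γ = diag(a, a, b)`, displacement

    G(t, Q) = GI(t) + GII(Q)
            = (Aa μ3(t), Aa μ4(t), Bb μ5(t))
            + (Aa Sigm(x1−x2), Aa C2 Sigm(C1 x0), Bb C4 Sigm(C3 x0)),

logistic gain `Sigm(x) = ν_max / (1 + exp(r (v0 − x)))`, and independent
Wiener processes scaled by `Σ = diag(σ3, σ4, σ5)`. The noise is additive, so
Itô and Stratonovich readings coincide; the sigmoid is globally Lipschitz, so
a pathwise-unique solution exists. The output signal `y = x1 − x2` is the
average membrane potential of the pyramidal population, the EEG-like
observable.

Assumptions carried throughout: `a, b > 0`; the deterministic inputs `μ_i`
are bounded (functional inputs must declare their bound, used by the moment
envelopes, whose hypotheses additionally require `μ_i ≥ 0`); the noise scales
are non-negative, and the ergodicity results need all `σ_i` strictly positive
constants (full ellipticity, queryable via `input_is_elliptic()`).

## Parameters, units and defaults

Everything runs on the seconds scale. Defaults are the classical values:
`A = 3.25` mV, `B = 22` mV, `a = 100` 1/s, `b = 50` 1/s (time constants 10
and 20 ms), `ν_max = 5` 1/s, `v0 = 6` mV, `r = 0.56` 1/mV, and connectivities
proportional to one synapse count `C` (`C1 = C`, `C2 = 0.8C`,
`C3 = C4 = 0.25C`), `C = 135` by default. The drive convention follows the
model equations verbatim: `μ4 = 220` and `σ4 = 1000` enter the `x4` equation
through `Aa[μ4 + C2 Sigm(C1 x0)] dt + σ4 dW4` on the seconds scale; no extra
unit conversion is applied. `ν_max = 0` is accepted so that the degenerate
linear model (sigmoid off) can be constructed for verification.

Scenario presets pin the regimes studied here: `alpha_C68 / _C135 / _C270 /
_C675` share `μ = (0, 220, 0)`, `σ = (10, 1000, 10)` and differ in `C`;
`phase_C135_smallnoise` uses `σ = (1, 200, 1)`. All presets start at
`X(0) = 0`: the model is geometrically ergodic under the preset noise, so the
long-run results are insensitive to this choice, and the zero state is the
one documented starting point of the phase-portrait regime.

## Exactly solved sub-flows and the integrators

The drift splits into a damped linear oscillator (matrix
`M = [[0, I], [−Γ², −2Γ]]`) and the displacement kick. Because `Γ` is
diagonal, `e^{Mt}` has diagonal blocks

    θ(t) = e^{−Γt}(I + Γt),   κ(t) = e^{−Γt} t,
    θ'(t) = −Γ² e^{−Γt} t,    κ'(t) = e^{−Γt}(I − Γt),

implemented as length-3 diagonals (`jr_kernel_blocks()`), valid verbatim for
any diagonal `Γ` including `a = b`, and for negative `t` (inverse flow). The
semigroup and commutation identities are enforced by tests at 1e-10 relative
tolerance.

Two ways of assigning the noise to a sub-flow give two Lie–Trotter maps, each
a composition of *exact* sub-flows:

* **OU integrator** (`"ou"`): momentum kick
  `P += Δt·GII(Q) + ∫ GI`, then the exact Ornstein–Uhlenbeck transition
  `X ← e^{MΔt}X + ξ`, `ξ ~ N(0, Cov(Δt))`.
* **Wiener integrator** (`"wiener"`): kick plus Gaussian increment
  `Σ ΔW`, then the deterministic linear flow `X ← e^{MΔt}X`.
* **Strang integrator** (`"strang"`): half linear flow, full stochastic
  kick, half linear flow — a second-order method for the noise-free model,
  still mean-square order one with noise (raising the stochastic order would
  require higher-order stochastic integrals, which is out of scope).
* **Euler–Maruyama** (`"em"`): the standard baseline.

The composition order of the Lie–Trotter maps is kick-first; a `commute`
flag reverses it (the theoretical guarantees hold either way). `∫ GI` over a
step is exact for constant `μ` and otherwise uses 5-point Gauss–Legendre
quadrature per step, since the model only assumes the integral is available.

For constant `Σ`, `Cov(Δt)` has the closed form with blocks
`¼Γ⁻³Σ²(I + κθ' − θ²)`, `½Σ²κ²`, `¼Γ⁻¹Σ²(I + κθ' − κ'²)`. For time-dependent
`Σ`, the covariance ODE `dC/dt = MC + CMᵀ + diag(0, Σ²(t))` is integrated
once per step size with fixed-step classical RK4 (100 substeps, `deSolve`)
and reused for every step. Gaussian increments are sampled through the
symmetric eigendecomposition square root with eigenvalues below 0 clipped at
tolerance 1e-12 — necessary because the position block of `Cov(Δt)` is
singular as `Δt → 0`. Steppers are vectorised over paths (a state is a
`6 × n` matrix), which is what makes the Monte-Carlo studies below cheap.

## Moment envelopes, pathwise bounds, calibration

From the convolution representation
`Q(t) = θ(t)Q0 + κ(t)P0 + ∫ κ(t−s) G(s, Q(s)) ds + ∫ κ(t−s) Σ dW(s)`
and the bound `0 ≤ G ≤ C_G` with
`C_G = (Aa(μ3max + ν_max), Aa(μ4max + C2 ν_max), Bb(μ5max + C4 ν_max))`:

* the mean envelope `θQ0 + κP0 ≤ E[Q(t)] ≤ θQ0 + κP0 + Γ⁻²(I − θ)C_G`
  (componentwise), with limits `[0, Γ⁻²C_G]`;
* a second-moment upper envelope (constant `Σ` only) whose positive-part
  indicator `1⁺(u)` is applied elementwise per time point, exactly as the
  estimate is derived;
* a dominating Gaussian process per component with mean
  `u(t) + Γ⁻²(I − θ)C_G` and variance `¼Γ⁻³Σ²(I + κθ' − θ²)`, giving the
  pointwise escape bound `P(X_i(t) ≥ x_th) ≤ 1 − F(x_th)` and the quantile
  curves plotted against simulated paths. Only pointwise-in-time,
  per-component bounds are provided; the momentum analogues and joint bounds
  are not.

Noise calibration inverts the quantile equation `F(x_th) = α` in the noise
scale; since the envelope mean is independent of `σ`, the root is unique and
found by bracketed root finding on `[0, σ_max]` (relative tolerance 1e-10),
with the degenerate case (threshold at the mean, `α = 0.5`) returning 0 by
convention. With `σ_i = 0` the bound degenerates to an indicator.

The same convolution formula doubles as an independent oracle for stepped
trajectories (`convolution_reconstruct()`): both integrals are discretised by
the left-endpoint rectangle rule on the trajectory's own grid (first-order
accurate). Unrolling the Wiener integrator shows it *is* that discretisation,
`Q(t_i) = θ(t_i)Q0 + κ(t_i)P0 + Σ_k κ(t_i − t_k)[G(t_k, Q_k)Δt + ΣΔW_k]`,
an exact algebraic identity that the tests check to 1e-12.

## Measuring mean-square order

`estimate_ms_order()` couples every scheme and every step size to one set of
Brownian paths: raw increments are generated on a reference grid
(`dt_ref = min(dt)/4` by default) and aggregated by summation to each coarser
dyadic grid, so coarse increments are exactly the sums of fine ones. The
reference solution is the Strang splitting on the fine grid — no closed-form
solution exists, so the reference choice is itself a method choice and is
recorded in the report. For the OU integrator the exact increment
`ξ = ∫ e^{M(Δt−s)} S dW` is rebuilt from the fine increments by a left-point
rectangle rule whose mean-square error is `O(dt_ref)`, the same order as the
reference. Errors are root-mean-square endpoint errors; the slope comes from
a least-squares fit in log–log, and its uncertainty from refitting on five
path groups.

Problem sizes used by the tests: `T = 1` s and 500 paths for the stochastic
studies at the `alpha_C135` scenario over `dt ∈ {4e-3, 2e-3, 1e-3, 5e-4}`;
the Wiener and OU splittings measure slopes ≈ 0.94 there. The noise-free
Strang study uses the one-notch-finer window `dt ∈ {2e-3, …, 2.5e-4}`,
because local octave slopes (2.46, 2.22, 2.07 on the coarser window) show the
noise-free dynamics only reach the asymptotic second-order regime below
`dt = 2e-3`; on the finer window the fitted slope is ≈ 2.13.

Two limitations surfaced by these measurements are worth stating. First,
Euler–Maruyama at the `alpha_C135` scenario does *not* display its asymptotic
order over `dt ∈ [5e-4, 4e-3]`: the dynamics live on a noisy limit cycle
near 10.75 Hz, and EM's phase bias at these step sizes exceeds a full cycle
over 1 s (its deterministic endpoint errors are even non-monotone in `dt`),
so the fitted slope is ≈ 0.4 — the quantitative face of EM's unreliability
at moderate steps, and the reason the corresponding endpoint-error check in
the test suite fails for EM while both splittings pass. EM does show slope
≈ 1.1 on the pure linear model and at `C = 68`, confirming the implementation.
Second, no scheme is exempt from coupling bias: the reference shares the
order-one constant of the splittings, which mildly flattens measured slopes
at the finest steps.

## Long-run behaviour

With fully elliptic noise the model has a unique invariant measure and is
geometrically ergodic, so a single long path estimates stationary quantities
from any starting point. `long_run()` discards a burn-in (default 10 s) and
subsamples with stride 10 (defaults chosen at desk scale; the invariant law
is insensitive to them, only estimator variance changes). `kde_density()` is
a plain Gaussian-kernel estimator on an explicit grid — explicit so densities
from different runs are comparable pointwise — with Silverman's rule-of-thumb
bandwidth by default. `time_average()` attaches batch-means standard errors,
since subsampled long-run states remain autocorrelated.

Mode counting reports local maxima above 5% of the global maximum *that are
prominent*: a counted pair of modes must be separated by a valley below 80%
of the smaller peak. The prominence requirement exists because at `C = 135`
the stationary density of `y` carries two shallow near-equal bumps about
1.3 mV apart — the turning points of the alpha oscillation — with valleys at
96–100% of the peaks, while the genuinely multimodal `C = 270` regime has
valleys at 57–71%; the 80% threshold sits in the wide gap between the two
cases. With it, the unimodal (`C = 68, 135`) → multimodal (`C = 270`) →
sharply-peaked (`C = 675`) progression is stable across replicates at the
test sizes (120 s runs, 20 s burn-in, `dt = 1e-3`).

`drift_check()` verifies the discrete Lyapunov condition empirically for
`V1(Q, P) = 1 + ‖P‖²/2 + 3‖ΓQ‖²/2 + ⟨P, ΓQ⟩`: transitions are grouped into
20 equal-count bins of `V1(X_i)` and the bin means of `V1(X_{i+1})` are
regressed on the bin means of `V1(X_i)`; a slope below one certifies the
contraction, valid for `Δt < 1/(2 max(a, b))` (0.005 s at default rates). For
larger steps the report flags the violated hypothesis instead of asserting.
Proof-internal constants (the drift coefficients, ergodicity rates) are
existence-only and are never represented as data; the regression estimates
empirical surrogates.

## Numerical choices and degenerate inputs

* State ordering is `(x0, …, x5) = (Q, P)` everywhere, including CSV output.
* `t_end/dt` must be integral within 1e-8 relative rounding; grids are exact
  multiples of `dt`.
* Sigmoid evaluation underflows to exactly 0 (or saturates at `ν_max`) for
  arguments beyond ±700/r mV; the strict range `(0, ν_max)` is a statement
  about exact arithmetic.
* Non-finite states abort a simulation with the offending step index.
* All stochastic test assertions use three standard errors (binomial,
  Monte-Carlo, or batch-means as appropriate) with sample sizes fixed in the
  tests.
* Monte-Carlo tests run 1000–4000 paths for envelope checks, 2000 paths for
  coverage curves, 2e4 transitions for drift regressions — sizes chosen so
  the whole suite stays at desk scale.

## What the scenarios do and do not emulate

The presets reproduce the stylised regimes of the model family: alpha-band
oscillation (`C = 135`, dominant spectral peak at 10.75 Hz in the worked
example), low-activity unimodal behaviour (`C = 68`), spiking/multimodal
behaviour (`C = 270`), and saturated peak-like behaviour (`C = 675`). They
are not EEG data: no measurement noise, no volume conduction, no
non-stationary drive, a single column rather than coupled areas
(multi-population and multi-area extensions are deliberately out of scope).
Passing tests certify properties of the model and its integrators, not fits
to recordings.

## Known limitations

* Envelopes and escape bounds cover the position components only, pointwise
  in time and per component; no joint or momentum bounds.
* The second-moment envelope and the escape machinery require constant `Σ`.
* The Strang map's mean-square order remains one with noise; no higher-order
  stochastic integrals are implemented.
* No adaptive step-size control; no spectral-gap or ergodicity-rate
  estimation; densities come from KDE only.
* Convergence measurements rely on a fine-step Strang reference, not an
  exact solution.
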