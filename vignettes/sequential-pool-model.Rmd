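---
title: "Modelling Ca2+-dependent neurosecretion with a sequential vesicle pool model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Ca2+-dependent neurosecretion with a sequential vesicle pool model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsim)
```

## The models

Secretory vesicles in adrenal chromaffin cells pass through a sequence of
maturation states before fusing with the plasma membrane. Capacitance
recordings after Ca2+ uncaging resolve the resulting release into a fast
burst, a slow burst, and a nearly linear sustained component. Two model
families explain this kinetic diversity:

* **Sequential Pool Model (SPM).** A large Depot feeds a Non-Releasable
  Pool (NRP) through Michaelis-Menten Ca2+-dependent recruitment,
  `k1(ca) = k1Max * ca / (K_M + ca)`. NRP vesicles prime reversibly into
  the Readily-Releasable Pool (RRP), and only RRP vesicles fuse, through
  a sequential sensor binding three Ca2+ ions followed by a fast final
  step (`k4`). The fast burst is the RRP emptying; the slow burst is NRP
  vesicles maturing through the RRP; the sustained phase is Depot
  recruitment.

* **Parallel Pool Model (PPM).** Two releasable pools (SRP and RRP) fuse
  in parallel through separate three-site sensors with slow and fast
  kinetics; the SRP-to-RRP conversion is slow and Ca2+-independent.

The SPM's distinguishing ingredient is a **Ca2+-dependent priming
catalyst**. The overall priming rates are

```
k2(ca)       = k20     + k2cat      * g(ca)
k_minus2(ca) = k_minus20 + k_minus2cat * g(ca)
g(ca)        = (ca / (K_D + ca))^n
```

with `g` the probability that the catalyst has bound its `n` Ca2+ ions
(independent, identical sites, instantaneous equilibrium). Because a
catalyst only lowers the transition-state energy, it cannot move the
NRP-RRP equilibrium: the package therefore never treats `k_minus2cat` as a
free parameter but derives it from the thermodynamic constraint

```
k_minus2cat = k2cat * k_minus20 / k20
```

so that `k2(ca)/k_minus2(ca) = k20/k_minus20` holds identically at every
Ca2+ concentration. This single assumption reproduces the otherwise
puzzling invariance of the fast-to-slow amplitude ratio under changing
Ca2+, while still letting elevated Ca2+ speed RRP refilling by orders of
magnitude.

```{r}
p <- spm_params()   # chromaffin-cell defaults (preset "spm_table1")
priming_rates(c(0.5, 25, 100, 1000), p)
```

At rest (0.5 uM) priming runs at 0.12 /s against 0.10 /s; at high Ca2+
both rates approach their catalysed ceilings (20 /s forward) with the
ratio pinned at 1.2.

## Parameters and their meaning

The built-in presets carry the published chromaffin-cell parameter sets:
recruitment `k1Max = 55` fF/s with `K_M = 2.3` uM, unpriming
`k_minus1 = 0.05` /s, catalyst `k20 = 0.021` /s, `k2cat = 20` /s,
`k_minus20 = 0.017` /s, `K_D = 100` uM, `n = 1`, and the fast sensor
`k3 = 4.4` /(s uM), `k_minus3 = 56` /s, `k4 = 1450` /s. Pools are carried
in femtofarads throughout — the capacitance proxy for vesicle membrane
area used by the recordings the model describes — so no conversion to
vesicle counts is ever made. The catalyst cooperativity defaults to
`n = 1`, the simplest variant; the rate law accepts any integer `n >= 1`.

The fusion sensor uses the standard three-identical-site scheme with
statistical factors (forward `3*k3*ca`, `2*k3*ca`, `k3*ca`; backward
`k_minus3`, `2*k_minus3`, `3*k_minus3`). With the default parameters the
analytic resting steady state then yields a spontaneous release rate of
1.66 fF/s for the wild type and 6.94 fF/s for the unclamped
synaptotagmin-null variant — the pair of observables that pins this
convention:

```{r}
spm_steady_state(0.5, p)$fusion_flux
spm_steady_state(0.5, p, "unclamped_syt_null")$fusion_flux
```

## Numerical integration

Simulations are driven by piecewise Ca2+ protocols (`ca_protocol()`):
constant segments, instantaneous steps (uncaging flashes), and
exponential relaxations. Integration uses the fifth-order Runge-Kutta
pair with Cash-Karp coefficients and adaptive step-size control (through
`deSolve`), restarted exactly at every segment boundary so that no
adaptive step straddles a Ca2+ discontinuity — an adaptive stepper loses
its order across a jump it does not know about. Defaults:
`rel_tol = 1e-8`, `abs_tol = 1e-10` fF, dense output every 1 ms (the
resolution scale of a capacitance recording). Every simulation starts
from the analytic steady state at the protocol's initial Ca2+ level
unless an explicit state is given.

Two bookkeeping series are integrated alongside the pools: the cumulative
capacitance `dCm` and the cumulative net Depot exchange `influx`. Their
combination gives a mass-conservation residual at solver accuracy
(quadrature on the output grid would be orders of magnitude coarser),
which the test suite holds below ten times the absolute tolerance.

```{r, fig.width = 6, fig.height = 4}
tr <- integrate_model("spm", p, ca_step_protocol(0.5, 25, t_step = 0.5),
                      t_span = c(0, 5.6))
autoplot(tr)
```

## Burst decomposition

Cumulative release is decomposed exactly as capacitance traces are
analysed experimentally: nonlinear least squares of

```
f(t) = A0 + A1 (1 - exp(-(t - t0)/tau1)) + A2 (1 - exp(-(t - t0)/tau2)) + A3 (t - t0)
```

over 5 s, with `A0` fixed to the baseline immediately before onset and
`t0` fixed at the inflection point of cumulative release (the maximum of
the central-difference first derivative after the stimulus). Fits use
Levenberg-Marquardt with a multi-start grid (`tau1` in {5, 20, 100} ms,
`tau2` in {0.1, 0.3, 1} s, amplitudes from the trace rise) because the
sum-of-exponentials surface has local minima; the best residual wins and
components are relabelled so `tau1 <= tau2`. Bounds keep all amplitudes
and the sustained slope nonnegative and `tau` within [1e-4, 10] s —
physical positivity plus the 5 s window. Fits whose time constants
separate by less than threefold are flagged `poorly_separated` (the
regime where the fast/slow distinction is experimentally ambiguous), and
fits whose total burst is within twice the residual RMS are flagged
`low_signal`.

```{r}
fx <- flash_experiment("spm")   # 0.5 -> 25 uM at 0.5 s
glance(fx$fit)
```

A subtlety worth knowing: the release-rate maximum sits about 10 ms
*after* the Ca2+ step, because the three-site sensor takes a few
milliseconds to load. The onset `t0` therefore lands at ~0.511 s for a
step at 0.5 s, and the fitted fast rate (~54 /s) describes release from
that inflection point on. With these parameters the fitted
`tau2/tau1` is ~13: the slow-burst rate equals the overall priming rate
at the post-flash Ca2+ level, `k2(25 uM) = 4.02` /s, so the separation is
set by the model itself rather than by the fitting procedure.

## The in-silico experiments

* `postflash_scan()` — the slow-component rate tracks `k2(ca)`: half the
  catalysed ceiling near `K_D`, saturating toward `k2cat` (= 20 /s) at
  very high Ca2+. This is exactly the logic by which the catalyst's
  `K_D` and `k2cat` were estimated from uncaging data.
* `preflash_scan()` — burst amplitudes are bell-shaped in resting Ca2+
  (recruitment rises with Ca2+; pools deplete at higher rest levels)
  while the fast/slow split stays nearly constant.
* `selective_depletion_recovery()` — a depletion pulse long enough to
  empty the fast component but spare most of the slow one, found by
  bisection against an explicit criterion (immediate-probe fast
  amplitude < 15 % of control, slow > 70 %), then probe flashes at
  increasing intervals. The fast component recovers at the expense of the
  slow one, since refilled RRP vesicles come from the NRP.
* `double_flash_recovery()` — two uncaging flashes with exponentially
  relaxing Ca2+ in between (`tau_relax = 5` s by default, an
  approximation chosen on the visual scale of the measured inter-flash
  decay, which is not tabulated). Only catalyst-bearing models (SPM,
  PPM+cat) recover the fast component while Ca2+ is still elevated; the
  classical PPM's Ca2+-independent SRP-to-RRP step imposes a ~10 s pause.
* `syt_null_experiment()` — two readings of synaptotagmin-1 deletion:
  `"unclamped"` removes the final fusion barrier (every RRP state fuses
  at `k4`, spontaneous release rises 1.66 to 6.94 fF/s, the fast burst
  disappears); `"destabilized"` multiplies `k_minus2` by 10 (the RRP
  drains into the NRP, leaving a tiny fast burst and a slightly enlarged
  slow burst).

Two identification rules deserve explanation because the experimental
literature leaves them implicit. First, in the double-flash analysis a
free-time-constant double-exponential fit of a response that has *no*
fast component will happily split the slow component in two and report a
spurious "fast" amplitude; the recovered fast amplitude is therefore only
credited when its time constant lies within a factor 5 of the first
flash's fast time constant, and scored zero otherwise. Second, with the
default relaxation (`tau_relax = 5` s) the residual Ca2+ at an 8 s
interval is ~5 uM, where fusion still outpaces refilling; the SPM's fast
recovery at 8 s is accordingly small in absolute terms (a few percent)
though strictly positive, while the PPM's is zero — the qualitative
ordering, which is the model-discriminating observation, is robust to the
waveform approximation even though the absolute recovery level is not.

## The closed-form burst model

For SNARE-mutation analysis the burst phase reduces to a two-pool linear
system `NRP <-> RRP -> F` with constant rates and no refilling. Its
solution is a sum of two saturating exponentials whose decay rates are
the roots of `lambda^2 - (k2 + k_minus2 + k3) lambda + k2 k3 = 0` and
whose amplitudes follow from the eigen-decomposition with
`A_fast + A_slow = V_tot` exactly (`V_tot` defaults to 113.6 fF, the sum
of the published fast and slow pool sizes; whether mutant fits should
share one `V_tot` is not settled, so it is exposed as a parameter).
`snare_scan()` sweeps the fusion rate `k3` — the rate constant mapped to
C-terminal SNARE-complex assembly — and shows the SPM's signature
prediction: slowing fusion simultaneously slows the fast burst *and*
shifts amplitude from fast to slow, because all amplitudes and rates are
functions of the same three constants. The measure-zero repeated-root
case is evaluated through the `(V_tot + c t) e^(-lambda t)` limit form.

`ppm_burst_scan()` provides the parallel-model comparator: fixed starting
pools (61.3 and 52.3 fF), each fusing at a single effective rate, the
RRP's being the independent variable. The SRP's effective rate defaults
to the slowest eigen-rate of its sensor cascade at the post-flash Ca2+
level (`sensor_drain_rate()`), making the reduced system exactly
biexponential; its fitted amplitude split is pool-determined and stays
flat as the fusion rate varies — the behaviour that cannot reproduce the
SNARE-mutant data with a single parameter change.

```{r, fig.width = 6, fig.height = 4}
autoplot(snare_scan(10^seq(0, 3, length.out = 25)), y = "fast_fraction")
```

## Synthetic data, noise, and what the tests show

`generate_fixture()` produces noisy synthetic capacitance traces by
integrating a model and adding seeded Gaussian noise to the cumulative
capacitance only — the observable of the emulated experiments — leaving
the pool series clean. This is a measurement-noise model: it emulates
recording noise on an otherwise deterministic system, not biological
trial-to-trial variability, channel noise, or drift, so
parameter-recovery results bound the fitting machinery's accuracy rather
than the model's identifiability on real cells. The default
recovery benchmark uses 0.5 fF noise on a (60 fF / 20 ms, 50 fF / 200 ms,
10 fF/s) trace over 100 seeds and requires median parameter errors below
5 %. All simulation paths are deterministic; the only randomness in the
package is this seeded noise, and it restores the caller's RNG state.

## Numerical choices and limitations

* Problem sizes: the test suite integrates flashes over 3-5.5 s windows
  at 1 ms output, runs recovery scans on 2-4 interval grids, and checks
  the solver against a fixed-step classical RK4 oracle at `dt = 1e-5` s
  over the first 1.5 s of the uncaging protocol.
* Degenerate inputs: zero Ca2+ drains the steady state to empty pools;
  an all-zero rate matrix raises an error rather than returning a
  singular solve; flat traces yield a flagged onset at the stimulus time.
* The explicit solver is appropriate because the stiffest rate (`k4`,
  sensor saturation) still resolves at step sizes the error control
  selects anyway; no implicit fallback is provided.
* Spatially heterogeneous Ca2+ (microdomains near channels) is outside
  the model: all protocols assume the spatially uniform Ca2+ of uncaging
  experiments.
* The inter-flash Ca2+ waveform and the PPM+cat rate adjustments are not
  tabulated in the source material; both are exposed as parameters with
  documented defaults (relaxation `tau = 5` s; SPM catalyst values).
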