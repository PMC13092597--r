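---
title: "Methods: global kinetic analysis of DNA strand separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: global kinetic analysis of DNA strand separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrmkin)
```

This vignette documents the model, the numerical choices, and the
validation strategy behind `ccrmkin`. It is written for a reader who
wants to audit or extend the analysis, not just run it.

## The mechanism

CcrM is a DNA N6-adenine methyltransferase that locally melts
("strand-separates") its recognition site before methyl transfer. The
package implements the four-step mass-action scheme

```
E + S  <-k1/k1r->  FS  <-k2/k2r->  GSI  <-k3/k3r->  GSp  <-k4/k4r->  E + Sp
```

with six species — free enzyme `E`, duplex substrate `S`, the bound
complex `FS`, the strand-separated intermediate `GSI`, the enzyme-bound
methylated product `GSp`, and released product `Sp` — and eight rate
constants. Units are µM and seconds throughout; association steps
(`k1`, `k4r`) are bimolecular (µM⁻¹s⁻¹), everything else first order
(s⁻¹).

Standard locks, mirroring the published analysis the fixtures come
from: `k1 = 100` µM⁻¹s⁻¹ (diffusion-limited association; only the ratio
`k1r/k1` is determined by the data), `k3r = 0` (methyl transfer is
irreversible), and `k4r = 1e-6` (product rebinding negligible on the
observed time scales). `k4 = 1.63` s⁻¹ floats for the wild type and is
locked at the wild-type value for the mutant fixtures, where product
release is much faster than chemistry and hence undetermined.
`ccrm_fixtures()` carries the seven published parameter sets (WT and
six recognition-loop mutants) with these locks attached.

Two derived equilibria summarize the energetics: `K1 = k1/k1r` (binding;
`Kd = 1/K1`) and `K2 = k2/k2r`, the stability of the strand-separated
intermediate. The central scientific claim encoded in the fixtures is
that mutations act mainly by destabilizing `GSI` (lowering `K2`) and by
slowing chemistry (`k3`), not by abolishing binding.

## Simulation

`simulate_mechanism()` integrates the mass-action ODEs with
`deSolve::lsoda` and a compiled C derivative (`src/ccrm_ode.c`),
`rtol = 1e-8`, `atol = 1e-12`. Two conserved sums — total enzyme
`E + FS + GSI + GSp` and total DNA `S + FS + GSI + GSp + Sp` — are
checked to 1e-6 relative accuracy in the property tests on random
rate sets spanning five orders of magnitude.

```{r}
wt <- ccrm_fixtures()$WT
tr <- simulate_mechanism(wt, species_state(E = 5, S = 1),
                         c(0.01, 0.1, 1))
tr
conservation_error(tr)
```

A small linear-algebra helper underpins several design choices:
`linearized_matrix()` builds the Jacobian of the excess-enzyme
(pseudo-first-order) system over `(S, FS, GSI, GSp)` and
`slowest_relaxation_rate()` returns its smallest eigen-rate — the rate
at which the slowest observable phase actually relaxes at a given
enzyme concentration.

## Observables

Three experiments constrain different parts of the scheme:

* **Tryptophan fluorescence** (binding/isomerization):
  `a3 * (E + cFS*FS + cGSI*GSI + cGSp*GSp)`.
* **Pyrrolocytosine (PydC) fluorescence** (strand separation):
  `a1 * (S + FS + cGSI*GSI + cGSp*GSp + cSp*Sp)`.
* **Radiochemical single-turnover methylation** (chemistry):
  `GSp + Sp + bkg2`, in µM product.

Stopped-flow traces are subject to a 2.5 ms dead time: the first
recorded point already corresponds to reaction age 2.5 ms, so the model
is evaluated at `observed_times + dead_time` (`apply_dead_time()`).
This matters: at 10 µM enzyme the pseudo-first-order binding rate is
over 1000 s⁻¹, so most of the binding amplitude is lost in the dead
time, exactly as in the real instrument.

No absolute fluorescence coefficients were ever published; the
generator defaults (`a1 = 1` with PydC factors 3/2/1.5, `a3 = 1` with
Trp factors 0.8/0.6/0.6) are package conventions chosen so the PydC
rise is dominated by `GSI` and the Trp signal quenches on binding.

## Synthetic data generator

`generate_full_dataset()` emulates the published designs:

* Trp series: 0.5 µM enzyme vs 2.5/5/7.5/10 µM DNA, 2 s;
* PydC series: 1.0 µM DNA vs 2.5/5/7.5/10 µM enzyme, 2 s;
* methylation: 0.1 µM DNA, 0.25 µM enzyme, 12 log-spaced points.

Fluorescence traces have 500 points: `t = 0` plus 499 log-spaced points
from 2 ms to 2 s, approximating logarithmic stopped-flow sampling.
Noise conventions: experiments are "collected" in triplicate and
averaged; the configured `sigma_fluor` (default 1% of trace amplitude)
and `sigma_radio` (default 5% CV, SD proportional to signal) are the
noise levels *of the averaged trace*, so each simulated replicate
carries `sigma * sqrt(3)`. Identical configurations and seeds produce
identical datasets; different sub-seeds drive the three experiment
blocks so they are independently reproducible.

One deliberate deviation from a naive reading of the design: the
methylation window auto-scales as `5 / slowest_relaxation_rate(rates,
E = 0.25)` rather than `5/k3`. At 0.25 µM enzyme against a ~5 µM
dissociation constant, binding is sub-saturating and the observed
single-turnover rate is roughly `k3` times the `GSI` occupancy — about
0.028 s⁻¹ for the wild type, an order of magnitude below
`k3 = 0.21 s⁻¹`. A `5/k3` window (~24 s) would truncate the product
curve at ~50% conversion and noticeably degrade `k3`/`k4` recovery; the
eigen-rate window (~180 s for WT) lets it plateau. The same physics is
asserted by a test that compares the fitted single-exponential rate of
a noiseless product trace with the slow eigenvalue of an independently
hand-built Jacobian.

What the generator does **not** capture: photobleaching or lamp drift,
inner-filter effects, pipetting-level replicate-to-replicate amplitude
variation, non-Gaussian counting error in the radiochemical assay, and
cofactor (SAM) depletion — the model assumes saturating cofactor
throughout, as the experiments were designed to ensure.

## Exponential pre-fits

`fit_double_exponential()` (rising double exponential) and
`fit_one_phase_decay()` characterize single traces the way
instrument software does. Rates are optimized in log10 space with the
amplitudes profiled out by linear least squares (variable projection)
over a 5x5 log-spaced multistart grid, which makes the fits independent
of starting guesses; near-degenerate rate pairs are flagged
(`ill_conditioned`). `prefit_initial_rates()` maps these to starting
values for the global fit — the fast PydC phase seeds `k2 + k2r`, and
the single-turnover rate, divided by the `GSI` occupancy implied by the
starting binding guess, seeds `k3`.

## Global fitting

`fit_problem()` + `fit_global()` perform weighted least squares over
all traces simultaneously with bounded Levenberg-Marquardt
(`minpack.lm::nls.lm`). Numerical choices that matter:

* **log10 parameterization** of rate constants and fluorescence
  coefficients enforces positivity and equalizes step sizes across
  constants spanning seven orders of magnitude.
* **`epsfcn = 1e-8`**: the forward-difference Jacobian step must sit
  above the ODE solver's output reproducibility (~`rtol`-level noise).
  With the `nls.lm` default (machine epsilon) the finite-difference
  derivatives are dominated by integration noise and the optimizer
  stalls in spurious local minima; with 1e-8 the same fits converge in
  ~10 iterations.
* **Seeded multistart**: the configured start is used as-is and the
  remaining starts perturb it multiplicatively (up to a factor 3); the
  lowest-SSR start wins. All randomness flows from `options$seed`.
* **Weights**: one sigma per trace (scalar, or per-point for the
  radiochemical points). For synthetic datasets,
  `dataset_fit_problem()` pools the replicate coefficient of variation
  across the radio points and rescales by the signal, because a
  per-point SD estimated from three replicates is itself ~50% noisy
  and using it directly distorts the weighting enough to push `k3`
  recovery errors past 5%.
* **Integration failures** during a step yield a large finite penalty
  residual instead of an abort, so the optimizer backs away.
* **Per-trace scale factors** are implemented as bounded
  `[0.8, 1.25]` nuisance parameters but default to locked at 1: the
  generator (like averaged triplicate data) has no trace-to-trace
  amplitude drift, and floating per-trace scales alongside the global
  output factors `a1`/`a3` is a pure ridge. Set
  `scale_floating = TRUE` when fitting data with acquisition drift.

Locks are honoured bit-identically — locked constants come back exactly
as supplied, never round-tripped through the optimizer.

## Confidence intervals

`profile_parameter()` computes profile-likelihood intervals: the
parameter is clamped on a grid, everything else is re-optimized
(warm-starting outward from the optimum), and the 95% bound is where
the re-optimized SSR crosses the F threshold

```
SSR_crit = SSR_min * (1 + qf(0.95, 1, N - P) / (N - P))
```

with bisection refinement in log space to 0.5%. The core
(`profile_objective()`) is generic; the test suite validates it against
the closed-form profile of a one-parameter linear regression, where the
F-threshold bound coincides with the classical t interval exactly.
`ci_table()` renders `best (lower–upper)` rows, flagging interval sides
that never crossed the threshold inside the profiled grid as open
(`<min` / `>max`) rather than inventing a number.

## Steady-state algebra

`steady_state_params()` gives the closed forms

```
D       = k2*(k3 + k3r + k4) + k2r*(k3r + k4) + k3*k4
kcat    = k2*k3*k4 / D
Km      = [k1r*(k2r*k3r + k2r*k4 + k3*k4) + k2*k3*k4] / (k1*D)
kcat/Km = k1*k2*k3*k4 / [k1r*(k2r*k3r + k2r*k4 + k3*k4) + k2*k3*k4]
```

Note the `k2r*(k3r + k4)` term in `D`: the forward release constant
`k4` appears there, consistent with the `k2r*k4` terms of the `Km` and
`kcat/Km` expressions. With the reverse constant in its place the three
expressions are mutually inconsistent (and `kcat/Km != kcat / Km` even
at `k3r = 0`); as written, evaluating the fixtures reproduces the
tabulated steady-state parameters of all seven enzymes at their printed
precision, with a single documented exception (the F125L `Km` computes
to 2.047 ≈ 2.0, printed as 2.1 — explainable only by unrounded fitted
inputs). `verify_against_simulation()` provides the independent check:
multiple-turnover initial velocities simulated at catalytic enzyme
(0.01 µM) over a substrate grid, fit to the hyperbolic rate law, agree
with the closed forms within 5% for every fixture.

```{r}
steady_state_params(wt)
fold_changes(wt, ccrm_fixtures()$F125L)
```

## Recovery and coverage studies

The acceptance-level test fits full synthetic wild-type datasets at 10
seeds (each fit prefit-seeded with a 2-start multistart) and requires
the fixed-seed fit and the across-seed medians of the `k2` and `k3`
errors to stay under 5%, plus 95% profile-interval coverage of the
truth consistent with 0.95 by an exact binomial test at α = 0.01. Ten
seeds is a deliberate compromise between statistical resolution and a
CI-friendly runtime (each fit integrates ~4000 observations' worth of
ODE solutions per Jacobian evaluation); the study size is a package
choice, and the same machinery runs unchanged at any seed count.

## Limitations

* The mechanism is minimal: no explicit cofactor binding step, no
  enzyme dimerization, no DNA rebinding after release (`k4r` locked
  near zero). These match the regime the designs probe.
* Fluorescence coefficients are conventions; only rate constants and
  their intervals are meaningful outputs of a fit to synthetic data.
* Profile grids default to a factor of 4 around the optimum; truly
  undetermined parameters (e.g. `k4` in mutant-like regimes) come back
  with open bounds, which is the honest answer, not a defect.
* The closed-form steady-state expressions assume `k4r` negligible; the
  locked 1e-6 value keeps simulation and algebra consistent to well
  under the 5% verification tolerance.
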