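# ccrmkin

Global kinetic analysis of DNA strand separation by the CcrM
methyltransferase.

CcrM is a cell cycle-regulated DNA N6-adenine methyltransferase
(recognition site 5′GANTC3′) that does something unusual before it
methylates: it locally melts the duplex, so its recognition contacts
target a single strand. This package implements the four-step kinetic
mechanism that quantifies that behaviour,

```
E + S  <-k1/k1r->  FS  <-k2/k2r->  GSI  <-k3/k3r->  GSp  <-k4/k4r->  E + Sp
```

where `FS` is the initial enzyme-DNA complex, `GSI` the strand-separated
intermediate (stability `K2 = k2/k2r`), `GSp` the enzyme-bound
methylated product, and `Sp` released product. Units are µM and seconds.

The package provides:

* a stiff mass-action simulator with a compiled derivative
  (`simulate_mechanism()`), conservation checks, a linearization helper
  (`slowest_relaxation_rate()`), and a pre-steady-state burst analysis
  (`simulate_burst()`);
* observable models for tryptophan fluorescence (binding),
  pyrrolocytosine fluorescence (strand separation), and radiochemical
  single-turnover product formation, with stopped-flow dead-time
  handling (`model_signal()`, `apply_dead_time()`);
* exponential pre-fits for trace characterization and start generation
  (`fit_double_exponential()`, `fit_one_phase_decay()`,
  `prefit_initial_rates()`);
* weighted global least squares over all experiments simultaneously,
  with locked/floating rate constants, log-space bounded
  Levenberg-Marquardt and seeded multistart (`fit_problem()`,
  `fit_global()`);
* profile-likelihood 95% confidence intervals with an F-test threshold
  (`profile_parameter()`, `ci_table()`);
* closed-form steady-state parameters kcat, Km, kcat/Km from the
  microscopic rate constants, cross-validated against simulated initial
  velocities (`steady_state_params()`, `verify_against_simulation()`);
* a seeded synthetic-data generator emulating the published
  experimental designs, for parameter recovery and coverage studies
  (`synthetic_config()`, `generate_full_dataset()`);
* plain-text trace/dataset I/O, YAML parameter configs, and JSON fit
  reports (`write_trace_file()`, `write_rates_config()`,
  `report_fit()`).

The seven published parameter sets (wild type and six recognition-loop
mutants) ship as fixtures in `ccrm_fixtures()`, with the standard locks
(`k1 = 100` µM⁻¹s⁻¹, `k3r = 0`, `k4r = 1e-6`; `k4` locked at the
wild-type 1.63 s⁻¹ for mutants) attached.

## Core formulas

Steady-state parameters from the microscopic constants:

```
D       = k2*(k3 + k3r + k4) + k2r*(k3r + k4) + k3*k4
kcat    = k2*k3*k4 / D
Km      = [k1r*(k2r*k3r + k2r*k4 + k3*k4) + k2*k3*k4] / (k1*D)
kcat/Km = k1*k2*k3*k4 / [k1r*(k2r*k3r + k2r*k4 + k3*k4) + k2*k3*k4]
```

Profile confidence threshold:
`SSR_crit = SSR_min * (1 + qf(0.95, 1, N-P)/(N-P))`.

## Worked example

Simulate the wild type, generate a full synthetic dataset, recover the
rate constants by global fitting, and profile `k2`:

```r
library(ccrmkin)

wt <- ccrm_fixtures()$WT
wt
#> Rate constants of the strand-separation scheme (uM, s):
#>   k1   = 100        [locked]
#>   k1r  = 528
#>   k2   = 23.2
#>   k2r  = 6.7
#>   k3   = 0.21
#>   k3r  = 0          [locked]
#>   k4   = 1.63
#>   k4r  = 1e-06      [locked]

steady_state_params(wt)
#> kcat = 0.147 s^-1, Km = 1.1 uM, kcat/Km = 0.133 uM^-1 s^-1

# full three-experiment synthetic dataset (4 Trp + 4 PydC traces + a
# single-turnover methylation time course; 1% / 5% noise)
ds <- generate_full_dataset(synthetic_config(seed = 42))

# seed the global fit from exponential pre-fits and run it
start <- prefit_initial_rates(ds$traces[[8]], ds$traces[[9]])
prob <- dataset_fit_problem(ds, rates = start,
                            options = list(multistart = 2, seed = 43))
fit <- fit_global(prob)
fit
#> Global fit: 9 traces, 4012 observations, 13 floating parameters
#> Weighted SSR = 4389.19
#> Rate constants of the strand-separation scheme (uM, s):
#>   k1   = 100        [locked]
#>   k1r  = 531.9
#>   k2   = 23.45
#>   k2r  = 6.686
#>   k3   = 0.2056
#>   k3r  = 0          [locked]
#>   k4   = 1.721
#>   k4r  = 1e-06      [locked]

# 95% profile-likelihood interval for k2
prof <- profile_parameter(prob, fit, "k2",
  grid = 10^fit$par[["k2"]] * exp(seq(log(1/1.3), log(1.3),
                                      length.out = 13)))
ci_table(list(prof))
#>   parameter     best    lower    upper open        formatted
#> 1        k2 23.45344 23.16677 23.74366 none 23.5 (23.2–23.7)
```

The fit recovers the generating `k2 = 23.2` within 1.1% and
`k3 = 0.21` within 2.1%, and the profile interval covers the truth.
The whole example runs in under a minute on one CPU.

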