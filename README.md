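# sheeppulse

Collective motion in small sheep groups emerges from *synchronised
intermittence*: each animal is either grazing at null speed or walking at
roughly constant speed, and cohesion comes from imitating the start/stop
decisions of group-mates rather than from steering. `sheeppulse` is an R
package for studying this mechanism end to end — for behavioural
ecologists analysing event-latency data from small-group tracking, and
for modellers interested in how a microscopic decision rule produces a
macroscopic traveling wave.

The core model assigns every individual two switching rates that depend
on the behind/ahead split of its group-mates along the axis of travel.
A stopped individual starts walking at rate

    K_A = mu_A + alpha_A * (A+)^beta_A * (N - A+)^(-gamma_A)

where `A+` counts group-mates already walking ahead of it, and a walking
individual stops at rate

    K_I = mu_I + alpha_I * (I-)^beta_I * (N - I-)^(-gamma_I),
    mu_I = mu_I* / N

where `I-` counts group-mates stopped behind it. The package provides:

* **model_core** — the parameter vector and rate formulas
  (`behavioural_params()`, `activation_rate()`, `inactivation_rate()`),
  with YAML/JSON serialization;
* **ibm_simulator** — an exact event-driven (Gillespie) simulation of N
  coupled walkers on a line, handling overtaking exactly
  (`run_gillespie()`), temporal departure/stop cascades
  (`simulate_departure_cascade()`), and group statistics
  (`group_statistics()`, `modulation_scan()`);
* **inference** — the data pipeline from raw 2D tracks to parameter
  estimates: `binarize_speed()`, `project_to_curvilinear()`,
  `detect_collective_events()`, `extract_latencies()`,
  `following_rates()` (the number-at-risk corrected rate
  `f(R, W) = 1/(R × mean latency)`), `fit_mimetic_params()` (log-domain
  regression with bootstrap CIs), `estimate_mu_I()` and
  `calibrate_mu_A()`, wrapped by `estimate_parameters()`;
* **kinetic_solver** — a mass-conserving upwind solver for the nonlocal
  transport–reaction density equations (`kinetic_solve()`), pulse
  observables (`pulse_metrics()`) and the finite-group resampling
  correction (`sample_groups_from_profile()`);
* **analytic_pulse** — the minimal model's closed-form sech² pulse:
  `gamma_shape()`, `steady_profile()`, `moving_fraction()`,
  `sensitivity_scan()`;
* **synthetic_data** — generators for field-like 1-Hz tracking tables
  (`generate_field_tracks()`) and cascade latency datasets
  (`generate_latency_dataset()`), so the whole analysis runs without any
  field recording;
* **pipeline** — `run_pipeline()` to chain configured stages with a JSON
  run manifest for byte-reproducibility.

## Worked example

Simulate departure cascades at the default ("kept") parameters, rebuild
following rates and re-estimate the parameters:

```r
library(sheeppulse)
p <- behavioural_params(N = 4L)
rec <- generate_latency_dataset(p, n_events = 500, kinds = "departure",
                                seed = 42)
fit <- fit_mimetic_params(rec, n_boot = 500, seed = 42)
fit
#> Mimetic rate fit: f(R, W) = alpha * W^beta * R^-gamma
#>   alpha = 0.3003  [0.2855; 0.3182]
#>   beta  = 0.6124  [0.5769; 0.6512]
#>   gamma = 0.7013  [0.6618; 0.7386]
#>   R^2 = 0.9940 over 13 cells
```

The estimates recover the generating values (0.3, 0.6, 0.7): `alpha` is
the imitation strength in s⁻¹, `beta` the amplification by walkers
already ahead, `gamma` the inhibition by the rest of the group. A
full-length stochastic realization and its cohesion statistics:

```r
traj <- run_gillespie(p, t_max = 1800, seed = 42)
group_statistics(traj, at_times = c(600, 1800))$at
#>   time_s dispersion distance_walked
#> 1    600       2.78           93.50
#> 2   1800       1.66          160.66
```

`dispersion` is the position range divided by N − 1 (meters per
neighbour); `distance_walked` is the cumulative path of the group's
center of mass. In the minimal model (`beta = 1`, `gamma = 0`,
`alpha_A = alpha_I = 0.5`, `mu_A = 0.02`, `mu_I = 0.08`, `v = 1`), the
group's density settles into a sech² pulse with shape rate
`gamma_shape(4, 0.5, 0.5, 1) = 1` m⁻¹ (peak `N*gamma/2 = 2` sheep/m) and
moving fraction `moving_fraction(p, "symmetric") = 0.2`, so the pulse
travels at 0.2 m/s; `kinetic_solve()` reproduces this from any initial
condition.

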