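---
title: "Coupled intermittent walks: model, inference and traveling pulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled intermittent walks: model, inference and traveling pulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheeppulse)
```

## The behavioural model

Grazing sheep in small groups move intermittently: each individual is
either stopped (head down, null speed) or walking at an approximately
constant speed $v$. Group cohesion arises not from steering but from
*synchronising the switches* between these two modes. `sheeppulse`
implements a double mimetic switching-rate model for this decision
process, the machinery to estimate its parameters from tracking data, and
its continuum (kinetic) counterpart, for which a closed-form traveling
pulse exists in a minimal limit.

Along the one-dimensional axis of collective travel, the group-mates of a
focal individual split into four pools: moving ahead ($A^+$), moving
behind ($A^-$), stopped ahead ($I^+$) and stopped behind ($I^-$). A
stopped individual starts walking at rate

$$K_A = \mu_A + \alpha_A \,(A^+)^{\beta_A}\,(N - A^+)^{-\gamma_A},$$

and a walking individual stops at rate

$$K_I = \mu_I + \alpha_I \,(I^-)^{\beta_I}\,(N - I^-)^{-\gamma_I},
\qquad \mu_I = \mu_I^\ast / N .$$

Only group-mates already in the *target* state and on the *relevant side*
stimulate a switch (walkers ahead pull; stoppers behind anchor); everyone
else inhibits it through the base of the negative exponent. Two
bookkeeping conventions deserve note:

* **Inhibitory base.** The formulas use $N - A^+$ (resp. $N - I^-$)
  literally, which counts the focal individual in its own inhibitory
  pool; since the others sum to $N - 1 - A^+$, the base is always
  $\ge 1$, so the negative power is always finite. The alternative
  convention ($N - 1 - A^+$, floored at 1) is available via
  `behavioural_params(focal_in_base = FALSE)`, but is not the default.
* **$0^0 = 1$.** When an exponent is exactly zero the corresponding
  factor is 1 even at base 0. The minimal model ($\gamma = 0$) relies on
  this.

Default parameter values are the retained one-decimal estimates for the
study system: $\alpha_A = 0.3$, $\beta_A = 0.6$, $\gamma_A = 0.7$ (start
side), $\alpha_I = 0.4$, $\beta_I = 0.5$, $\gamma_I = 0.5$ (stop side),
$\mu_A = 0.0055\ \mathrm{s^{-1}}$ (one spontaneous departure per
individual per ~3 minutes), $\mu_I^\ast = 0.08\ \mathrm{s^{-1}}$, and
$v = 1\ \mathrm{m\,s^{-1}}$ (the order of magnitude of the walking mode;
the grazing mode is an order of magnitude slower).

## Exact stochastic simulation

`run_gillespie()` generates statistically exact realizations of the
coupled $N$-walker process. Between events, rates are constant, so the
next switch is drawn from the total-rate exponential. Two kinds of
instants change the rates: switching events themselves, and *overtaking
instants*, when a mover's abscissa crosses a stopped walker's and the
behind/ahead partition changes. The simulator advances to whichever comes
first, rebuilds all pools, and redraws waiting times (valid by
memorylessness), keeping the realization exact with piecewise-constant
rates.

Numerical choices:

* "Ahead" means strictly greater abscissa; exact position ties are broken
  by walker index (lower index counts as behind), making replays
  deterministic and order-independent.
* At an overtaking instant the mover is nudged $10^{-9}$ m past the
  walker it reached, so the partition is unambiguous on the following
  open interval. The bias is far below any physical scale (positions
  are meters).
* The default initial condition is all walkers stopped at i.i.d. uniform
  positions on a 1 m segment — a dense grazing start.

Departure and stop *cascades* (`simulate_departure_cascade()`,
`simulate_stop_cascade()`) use the purely temporal variant with frozen
positions: the initiator counts in every focal's stimulating pool and
stage $W \to W + 1$ lasts an $\mathrm{Exp}\{(N - W) K(W)\}$ time. This is
the appropriate model for event-level statistics because the event-rate
formulas are position-free once the initiator is in front.

## Rate inference from tracking data

`estimate_parameters()` chains the full data pipeline:

1. **Binarization** (`binarize_speed()`): a sample is "moving" when its
   speed strictly exceeds 0.3 m/s — the log-scale midpoint between the
   grazing (~0.1 m/s) and walking (~1 m/s) modes — followed by a
   debouncing pass merging runs shorter than 2 samples.
2. **Projection** (`project_to_curvilinear()`): tracks are reduced to 1D
   by projecting onto the simplified (Ramer–Douglas–Peucker, 0.5 m
   tolerance) polyline of the group's center of mass; abscissae are arc
   lengths along that path, increasing in the travel direction. Terminal
   segments extend beyond their end vertices so walkers ahead of the
   final center-of-mass position keep meaningful coordinates.
3. **Event detection** (`detect_collective_events()`): a collective
   departure runs from the first start after an all-stopped period to the
   last start, provided the whole group reaches the moving state before
   relapsing; stops are the mirror image. Events whose initiator reverted
   before the last follower switched are discarded — the stimuli at work
   are then ill-defined.
4. **Latencies and rates** (`extract_latencies()`,
   `following_rates()`): each follower switch yields a latency annotated
   with the counts ($W$ already switched, $R$ still at risk) when its
   clock started. With $R$ candidates racing, the pooled waiting time has
   rate $R \cdot f$, so the per-individual following rate is
   $f(R, W) = 1 / (R \times \text{mean latency})$ — the standard
   competing-risks (number-at-risk) correction. Cells with fewer than 3
   latencies are dropped (the pooled design across group sizes 2, 3, 4, 8
   leaves 13 cells at study scale).
5. **Regression** (`fit_mimetic_params()`): ordinary least squares of
   $\log f$ on $(\log W, \log R)$, unweighted across cells by default (a
   count-weighted variant is available); $\alpha = e^{\text{intercept}}$,
   $\beta$ is the $\log W$ coefficient and $\gamma$ minus the $\log R$
   coefficient. Confidence intervals come from a seeded nonparametric
   bootstrap over latency records (1000 resamples by default), which for
   this regression is equivalent in practice to distribution-free
   posterior sampling.

Two estimators deserve caveats, both visible in the tests:

* **Sampling-rate quantization.** At the field sampling period (1 s),
  stop cascades resolve within one or two samples; ties are imputed at
  half a sample and the switch *order* within a tied sample is
  arbitrary. This washes out the stop-side exponents in fully realistic
  end-to-end runs while leaving the departure side (latencies of several
  seconds) and both imitation strengths identifiable. Cascade-level
  data, which are continuous in time, recover all six parameters to one
  decimal.
* **Spontaneous stop rate.** `estimate_mu_I()` regresses the per-group-
  size rate (inverse mean collective-move duration) on $1/N$ through the
  origin. Within the model itself, the first stop in a group of $N$
  movers each stopping at $\mu_I^\ast/N$ occurs at rate $\mu_I^\ast$
  regardless of $N$; the estimator is therefore calibrated for
  durations that scale with $N$ per individual (as the field
  observations did), and the tests exercise it on durations drawn from
  the per-individual law.

$\mu_A$ is not identifiable from events (aborted departures are
indistinguishable from grazing micro-moves), so `calibrate_mu_A()`
matches simulated mean ranged distances to per-group-size targets over a
candidate grid — ranged distance is strictly increasing in $\mu_A$, which
the suite verifies.

## Kinetic (density) equations

`kinetic_solve()` integrates the continuum counterpart: densities
$A(x,t)$ (moving) and $I(x,t)$ (stopped) exchange mass at nonlocal rates

$$K_A(x) = \mu_A + \alpha_A S_A(x)^{\beta_A} (N - S_A(x))^{-\gamma_A},
\qquad S_A(x) = \int_x^\infty A\,du,$$

(and mirrored for $K_I$ with $\int_{-\infty}^x I\,du$), while $A$ is
advected at speed $v$. Discretization choices:

* Explicit Euler in time with $\Delta t = 10^{-2}$ s by default, and
  first-order conservative upwind transport with zero-flux ends; mass is
  conserved to round-off and asserted to $10^{-8} N$ at every snapshot.
* $\Delta x = 0.05$ m by default, resolving the ~meter-scale pulse with
  dozens of nodes while satisfying $v \Delta t \le \Delta x$.
* The stimulating integrals are right/left cumulative sums including
  half of the focal cell; the inhibitory base $N - S$ is clamped below
  at 1, the density counterpart of the focal-included microscopic base
  (and necessary, since the unclamped expression diverges when all mass
  is stimulating).
* The domain is a static interval sized for the run (pulse travel plus a
  generous margin); a tail-mass assertion (outermost 2 m below
  $10^{-6} N$ by default) guarantees the boundaries never matter. This
  keeps conservation exact without a co-moving frame.

Being first-order, the scheme carries numerical diffusion
$\tfrac{1}{2} v \Delta x (1 - v\Delta t/\Delta x)$. Observables that are
structurally fixed (the symmetric-case moving fraction and speed) come
out exact; shape-dependent observables (width; the asymmetric-case speed)
converge linearly in $\Delta x$, and the suite verifies both the
shrinkage rate and Richardson extrapolation onto the analytic values.

## The minimal model and its traveling pulse

Setting $\beta_\bullet = 1$, $\gamma_\bullet = 0$ keeps only spontaneous
switching and linear imitation. The steady regime combines a flat moving
fraction $b_s^\ast$ with a sech² density pulse

$$\eta_s(x,t) = \frac{N\gamma}{2}\,
  \mathrm{sech}^2\!\big(\gamma(x - b_s^\ast v t)\big),
\qquad \gamma = \frac{N(\alpha_A + \alpha_I)}{4v},$$

which integrates to $N$ and travels undeformed at $v b_s^\ast$.
Substituting into the moving-frame profile equation
$(n')^2 - n n'' - \frac{\alpha_A+\alpha_I}{v} n^3 = 0$ shows the residual
is $n^2\mathrm{sech}^2 \cdot (2\gamma^2 - (\alpha_A+\alpha_I)N\gamma/2v)$,
which pins the shape rate to the linear-in-$N$ expression above;
`pulse_ode_residual()` checks this to round-off, and the solver's steady
width at $N = 2$ (where a square-root law would predict a visibly
different width) confirms it dynamically.

The moving fraction has three closed forms (`moving_fraction()`): the
general quadratic root for $\alpha_A \ne \alpha_I$ (the printed "+"
branch; the other root leaves $[0,1]$ whenever $\mu_A > 0$), the
symmetric case $\mu_A/(\mu_A + \mu_I)$, and the group-size-regulated
variant $\mu_A/(\mu_A + \mu_I^\ast/N)$. Near symmetry the general root is
evaluated as the symmetric formula when $|\alpha_A - \alpha_I| <
10^{-12}$ (continuity is verified against the numeric limit). One edge
case worth recording: at $\mu_A = 0$ the general branch with promoted
departure imitation returns the *self-sustained moving* root
$1 - 2\mu_I/(N(\alpha_A - \alpha_I))$, not 0 — the quadratic factors and
the printed branch selects the nontrivial solution; only the symmetric
and variant forms vanish with $\mu_A$.

`sensitivity_scan()` evaluates $b^\ast(N)$ families around the symmetric
base ($\alpha = 0.5$, $\mu_A = 0.02$, $\mu_I = 0.08$): the symmetric case
is flat in $N$; promoting $\alpha_A$ by as little as 0.1% drives
$b^\ast \to 1$ at large $N$ and promoting $\alpha_I$ drives it to 0;
under the variant scaling, promoted stopping becomes non-monotone with an
interior maximum before declining at very large $N$.

## Synthetic field data

`generate_field_tracks()` emulates the raw material of the study: 1-Hz
2D positions for groups of 2, 3, 4 and 8 (8 replicate groups each,
1800 s). The 1D simulator output is embedded along a piecewise-straight
path with a fresh heading per collective bout (uniform within ±60° of the
previous one — pure plumbing, since the analysis is 1D after projection),
plus grazing-state jitter (independent isotropic offsets tuned to a mean
apparent speed of 0.1 m/s, below the binarization threshold by
construction) and 5 cm isotropic measurement noise. With zero jitter and
noise and a single heading, projection inverts the embedding to round-off
— the suite's reference identity.

What the generator deliberately does *not* emulate: pen boundaries
(80 × 80 m), perception limits, heading dynamics within bouts,
individual heterogeneity, and grazing drift of stopped animals. Passing
end-to-end tests therefore validate the *pipeline* under the model's own
assumptions, not the behavioural model against real sheep.

## Problem sizes used by the test suite

The suite runs entirely from code at desk scale: 1000 stochastic
realizations for the cohesion statistic (t = 1000 s, N = 4); 2000
cascades per group size for one-decimal parameter recovery; 150
realizations at N = 100 (t = 400 s) against the solver profile and 3000
at N = 4 for the finite-size resampling correction; solver horizons of
300–600 s on domains of 100–250 m. These sizes were chosen so each
statistic's Monte-Carlo error sits well inside the tolerance it is tested
at.

## Known limitations

* The event-driven simulator is exact but O(N²) per event in pool
  rebuilding; it is comfortable to N of a few hundred, not thousands.
* The kinetic solver is first-order; shape-dependent observables carry
  O(Δx) error (quantified above). Higher-order or co-moving schemes are
  out of scope.
* At the biological parameter point, the model's steady neighbour
  spacing comes out around 1.6–1.7 m per sheep (consistently between the
  stochastic and continuum routes), somewhat looser than the ~1 m the
  source material quotes for the same statistic; and ranged distance
  *decreases* with group size under the printed spatial rates (large
  groups abort departures more), so distance-based calibration targets
  should be per-group-size.
* 1-Hz sampling fundamentally limits stop-side exponent recovery from
  track data (see the quantization caveat above); cascade-level data do
  not share the limitation.
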