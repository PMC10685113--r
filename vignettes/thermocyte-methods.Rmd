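---
title: "Models and methods behind thermocyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermocyte}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocyte)
```

`thermocyte` is a software-in-the-loop companion to an open-source,
Arduino-class stage-top temperature controller for live-cell imaging: a
PID-heated aluminium waterblock warms recirculating artificial CSF which is
carried to the imaging dish, while a second, constant-power polyimide strip
around the dish perimeter counters ambient losses. The package simulates
that closed loop, characterises temperature logs the way the hardware was
characterised (latency, hold stability), and implements the downstream
live-cell analytics: ΔF/F calcium-transient kinetics, circularity
morphometrics, viability summaries and the associated comparison
statistics. Everything is exercisable on seeded synthetic data, so the full
pipeline is testable without hardware, microscopes or downloads.

## The control law

`pid_step()` implements the textbook discrete PID on the set-point error
$e_t = T_{set} - T_{meas}$:

$$u_t = \mathrm{clamp}\!\left(k_p e_t + k_i \textstyle\sum_j e_j\,\Delta t
      + k_d \frac{e_t - e_{t-1}}{\Delta t},\; u_{min}, u_{max}\right)$$

Design choices, all configurable through `pid_params()`:

* **Derivative on the raw error**, no filtering, forced to zero on the
  first step after a reset. The firmware formulation prints an unfiltered
  $de/dt$ term; whether its gain was 0 or 1 in deployed code is not
  documented, so `kd` defaults to 0 and is exposed.
* **Gains** default to `kp = 20`, `ki = 0.05`, `kd = 0` (duty per °C
  units, 1 s interval). These are the package's own choice: they saturate
  the heater until the error falls below 0.05 °C and then let the integral
  remove the steady-state error, giving a stable, mildly overshooting loop
  on the default plant. The original firmware gains live in supplementary
  hardware code and are not published.
* **Anti-windup by integral clamping** (`integral_limit`, default
  $1/k_i$ so the integral term alone can just saturate the heater), the
  scheme typical of small microcontroller PID implementations; no
  back-calculation.
* Duty is kept **normalised to [0, 1]** internally; `duty_to_pwm8()`
  provides the 8-bit firmware view.

## The thermal plant

`step_plant()` integrates a deliberately minimal two-node
lumped-capacitance model — the simplest structure that reproduces the
observed block-leads-dish dynamics:

$$C_b \dot T_b = u P_{max} - k_{ba}(T_b - T_a) - q\,(T_b - T_d)$$
$$C_d \dot T_d = P_d + q\,(T_{in} - T_d) - k_{da}(T_d - T_a), \qquad
  T_{in} = T_a + k_{tube}(T_b - T_a)$$

with advective conductance $q$ = flow × volumetric heat capacity
(2 mL/min × 4.18 J/(mL·°C) by default, the documented operating flow).
The tube between block outlet and dish inlet is folded into a single
retention factor $k_{tube}$: the fluid arrives carrying that fraction of
the block's excess temperature, so heat is intentionally *not* conserved
across the tube. The block's return line is taken from the dish
(closed recirculation), hence the $q(T_b - T_d)$ advective loss term.
Integration is forward Euler with internal sub-stepping capped at one
fifth of the smallest nodal time constant; the suite checks that halving
the step changes trajectories by well under 0.1 °C. Pump pulsatility,
evaporation, CO₂ and spatial gradients are out of scope (the reported
~2 °C centre-to-periphery dish gradient is carried as a reporting field
only).

Ambient temperature defaults to 20 °C, the value stated alongside the
published latency measurements (a figure caption elsewhere says
"approx. 25 °C"; the body text value was used).

## Latency, protocols and calibration

The hardware was characterised by three heat/hold/cool cycles and by the
per-cycle heating and cooling latency of each thermocouple. The published
description never defines the latency criterion precisely, so
`measure_latency()` operationalises it as *banded arrival time*: the time
from phase start until the channel first enters
$[\mathrm{target} \pm \mathrm{band}]$ and stays inside for at least a
dwell time, defaulting to band = 0.5 °C and dwell = 0 s. Heating targets
the set point, cooling targets ambient. `run_protocol()` gates phase
transitions on the dish channel (the slowest node) and cuts all heater
power — including the dish strip — during cooling.

Physical constants of the real rig (thermal masses, loss coefficients)
are unpublished, so the shipped `plant_params()` defaults were produced by
`calibrate_plant()`: a bounded, derivative-free Nelder–Mead search (run in
a logit-transformed box, so it is deterministic) minimising the sum of
squared relative errors between simulated and published 37 °C latencies —
dish 5.50/5.44 min and block 1.68/5.85 min for heating/cooling. With the
shipped defaults a closed-loop three-cycle simulation reproduces all four
within 6 %. This is *self-consistency* of controller + plant against the
printed dynamics, not an independent validation: many parameter sets could
fit four numbers, and only relative (not absolute) heat capacities are
identified.

`log_stats()` reports mean, sample sd ($n-1$), min, max, range and IQR
(linear-interpolation quantiles; neither convention is stated in the
source material) over a window, with `"after-first-reach"` starting at the
first entry into the set-point band — the windowing used for the published
hour-long 37 °C stability trial. The gravity-feed helpers
`hydrostatic_pressure()` ($p = \rho g h$) and `poiseuille_flow()`
($Q = \pi \Delta P r^4 / 8 \eta L$) size a pump-free perfusion line.

## ΔF/F and transient detection

A calcium transient is defined operationally: **a period of ΔF/F at or
above 0.5 lasting at least 2 s**. `detect_transients()` is faithful to
that sentence — events are maximal contiguous above-threshold runs, never
merged across sub-threshold gaps, with width the run duration, height the
run maximum and AUC the rectangle-rule integral $\sum \mathrm{dff}/f_s$
over the run. Three conventions deserve explanation:

* **≥ rather than >.** The source uses both phrasings ("greater than
  0.5" in the methods text, "greater than or equal to" in the figure
  captions). The inclusive form is used so that a pulse whose
  above-threshold span is exactly the minimum width is not lost to
  strict-inequality sampling at finite $f_s$.
* **Rectangle rule rather than trapezoid.** With width defined as
  $n/f_s$ samples, the rectangle sum makes the invariant
  $\mathrm{auc} \ge \mathrm{threshold} \times \mathrm{width}$ an identity
  and renders a rectangular pulse's AUC exactly height × width; a
  trapezoid over the same run spans $(n-1)/f_s$ and violates the bound
  for barely-supra-threshold events.
* **De-noise first, then normalise.** `analyze_trace()` box-smooths the
  raw trace (default 1 s window), then estimates F0 and forms ΔF/F —
  the order used in the original analysis. It also keeps the
  percentile baseline's noise bias at the smoothed noise level.

F0 is a rolling low percentile (`estimate_baseline()`, default 20th
percentile over a 30 s window, edge-truncated, floored at a small positive
fraction of the trace median). The percentile trades two biases: with
transients occupying a fraction $o$ of a window, any percentile below
$1 - o$ ignores them; under Gaussian noise of sd $\sigma$ the $p$-th
percentile sits $z_p\sigma$ *below* the true baseline, inflating every
ΔF/F value by roughly $z_p\sigma/F_0$ and widening detected events. At the
20th percentile on a smoothed trace this bias is ~2 % of F0 for the noise
levels the generator emulates, while windows remain robust to transients
occupying up to half their span. ΔF/F is a ratio, so the whole pipeline is
exactly invariant to detector gain — multiplying a raw trace by any
positive constant changes no detected event.

Sampling rate is carried explicitly on every trace (`fs`); the synthetic
default is 5 Hz (the original acquisition rate is not stated; all
durations are computed in seconds via `fs`, so nothing depends on the
default). Published absolute peak widths (11.14 s vs 7.14 s) depend on the
original, unpublished detection code path and are treated as non-gated
observations, not reproduction targets.

`summarize_cell()` yields per-cell peak frequency (events/min), mean width
and mean AUC, and the activity rule — *active* means at least one event
passed both criteria; inactive cells carry `NA` means and are excluded
from event-level statistics. `summarize_cells()` exposes both analysis
routes: per-cell summaries, and events pooled across cells (attribute
`"events"`), matching the two ways group comparisons are commonly made.

## Comparison statistics

`compare_groups()` wraps the Welch unpaired *t*-test and the Mann–Whitney
U test (exact when sample sizes permit and no ties, otherwise the
tie-corrected normal approximation). Degenerate zero-variance inputs with
equal means return $t = 0, p = 1$ rather than erroring.
`compare_regressions()` fits per-group least-squares lines and tests
either slope equality (the group × covariate interaction of the pooled
model — the baseline height-vs-width comparison) or the group intercept
difference under a shared slope (ANCOVA — the stimulated-condition
comparison). The suite checks both against enumeration and permutation
oracles.

## Morphometrics and viability

Circularity is $4\pi \cdot \mathrm{area}/\mathrm{perimeter}^2$: 1 for a
perfect circle, falling towards 0 along the amoeboid-to-ramified
morphology axis. For label masks, `measure_regions()` takes area as the
pixel count and estimates perimeter with a **Crofton multi-direction
estimator**: boundary crossings are counted along rows, columns and both
diagonals and combined via the Cauchy–Crofton relation
$P \approx \tfrac{\pi}{8}\,(c_0 + c_{90} + (c_{45}+c_{135})/\sqrt2)$.
Raw boundary-pixel counting overestimates a circle's perimeter by ~27 %
and would push circle circularity to ~0.6; the Crofton estimator is
within 1 % on digital circles of radius ≥ 10 px and within ~5 % on convex
shapes generally (measured circularities may exceed 1 by up to ~0.1 for
small squares and are reported unclipped). Because the original analysis
used a different (unspecified) perimeter convention, absolute published
mean circularities (0.761 vs 0.610) are estimator-sensitive and not
reproduction targets. Scale invariance is tested by re-rasterising shapes
at larger radius, not by pixel replication — replicated pixels create
genuine 2–3 px staircase structure that any contour-length estimator
rightly measures.

`viability_summary()` is the stained/total bookkeeping (percentages
rendered to one decimal, as conventionally reported), and `bom_table()` /
`bom_total()` carry the build's bill of materials with prices in exact
integer cents so the €201.00 total is free of binary-float drift.

## The synthetic generators

`gen_traces()` emulates what the analysis assumes about real recordings:
a baseline $F_0$ decaying exponentially at a configurable fractional rate
per minute (photobleaching), transient kernels that rise linearly and
decay exponentially, multiplicative structure
$F = F_0(1 + \sum \mathrm{kernels}) + \mathrm{noise}$, and additive
Gaussian noise expressed in ΔF/F units. Defaults — chosen once, by
analysis of the kernel, to represent a realistic 3-minute baseline trial —
are 1 event/min, amplitudes 0.8–1.2 ΔF/F, 0.5 s rise, 5 s decay
constant, noise sd 0.05, 5 Hz: the weakest event then stays above the
0.5 threshold for ≈ 2.5 s, so every injected event exceeds both detector
criteria with margin.

Arrivals are a **hard-core renewal process**: exponential gaps shifted by
a 10 s refractory period, with the exponential rate corrected so the mean
rate stays exactly `event_rate`. A plain Poisson process would
occasionally overlap kernels, fusing events at generation time and making
per-event ground truth (onset, width, AUC) ill-defined; the refractory gap
keeps ground truth exact while leaving counts within a few percent of
Poisson statistics. `GroundTruth` records each event's analytic
above-threshold width (`nominal_event_width()`), so recovery tests compare
like with like.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: motion and focus drift, segmentation errors,
spatially correlated noise, indicator photochemistry (dye kinetics are
temperature-dependent), cell-to-cell baseline heterogeneity beyond the
bleaching term, and genuinely overlapping calcium events. Masks from
`gen_label_mask()` are circles, ellipses and smooth harmonic blobs, not
ramified microglial silhouettes; they exist to validate geometry
estimators against closed forms (circle exactly; ellipse via the
Ramanujan II approximation, relative error < 10⁻⁶ at the generated aspect
ratios). `gen_movie()` paints traces into mask regions with optional
pixel noise and round-trips exactly through `extract_traces()` at zero
noise.

All generators and simulators draw from isolated, seeded RNG streams:
reruns are byte-identical and the caller's global RNG state is never
touched.

## Problem sizes and numerical tolerances

The shipped test suite uses: 1000 random 50–60-sample traces against the
brute-force detector oracle; a 100-cell, 180 s, 5 Hz cohort for recovery
(injected rate recovered within 2 standard errors; mean width and AUC
within 10 %); three-cycle closed-loop simulations at 1 s control
intervals for the latency checks (all four published 37 °C latencies
within 10 %); and enumeration/permutation oracles at n ≤ 8 and B ≤ 2000
for the statistics. Step-size convergence is asserted at < 0.1 °C under
halving. Calibration self-consistency recovers latencies of a known plant
to < 5 % from a 25 %-perturbed start.

## Known limitations

* The plant is two-node and linear; it cannot represent radiative or
  strongly nonlinear losses, nor the dish's spatial gradient.
* Calibration fits four numbers with six parameters: the result is a
  plausible, dynamics-matching parameter set, not a physical measurement.
* The transient detector is deliberately the printed contiguous-run rule;
  it has no prominence logic, so overlapping physiological events merge.
* The Crofton perimeter's few-percent bias means absolute circularity
  comparisons across software require a shared estimator.
* Hour-long stability statistics can be computed from any imported log
  via `read_temperature_log()` + `log_stats()`, but the package ships no
  recorded hardware logs; simulated logs stand in for structure, not for
  measurement.
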