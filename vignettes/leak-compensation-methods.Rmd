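---
title: "Methods: leak-flow compensation and the simulated ventilation bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leak-flow compensation and the simulated ventilation bench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npvleak)
```

## The physical model

Nasopharyngeal ventilation is an open system: gas delivered through the
nasopharyngeal tube (NPT) reaches the pharynx and splits between the
patient's airway and an unconfined leak to atmosphere.  Treating flows as
currents and pressures as potentials, the bench is a three-branch network
meeting at the pharyngeal node:

* a source branch — the free-flow delivery device, modelled as a Norton
  source: constant generator flow `q_gen` in parallel with a linear valve
  resistance `r_val`;
* the NPT branch and the leak branch, each a Rohrer resistor,
  `ΔP = k_L·V̇ + k_T·V̇²`, capturing laminar plus turbulent losses;
* the patient branch: an ideal flow generator during spontaneous breathing
  (the respiratory flow is imposed by the patient), or a series
  resistance–compliance load `r_p`, `c_p` during mandatory breaths.

Kirchhoff's current law at the node gives `V̇NPT = V̇LEAK + V̇RES`, with
inspiratory flow positive.  Kinetic, elastic and inertial pressure
components of the tubing are neglected: breathing stays below 1–2 Hz, the
tube flow essentially never reverses, and pressures are far too low for
compressibility to matter.  Only the resistive component is kept, which is
what makes the leak channel invertible from pressure alone.

Canonical units are L/s, cmH2O and seconds everywhere inside the package;
L/min and mL appear only at I/O boundaries, converted by exactly 60 and
1000 (`lpm_to_lps()` and friends).

## Characterisation and inversion of the leak channel

During apnoea all tube flow escapes through the leak, so stepping the
delivered flow (0 to 20 L/min for children, 0.5 L/min increments — 41
levels including zero) and reading the plateau pharyngeal pressure samples
the leak's flow–pressure curve directly.  `fit_rohrer()` is linear least
squares in the basis `{V̇, V̇²}` with no intercept — the Rohrer form has
exactly two free coefficients — plus an active-set non-negativity clamp:
if the unconstrained fit turns a coefficient negative, the two single-term
boundary fits are compared by residual sum of squares.  Goodness of fit is
reported as MSE together with normalised scores in the *fit* convention
(`1` is perfect, `0` is no better than predicting the mean), which is the
convention under which good bench fits report values like 0.988/0.999.

`invert_rohrer()` solves the quadratic for flow.  Two numerical choices:

* the cancellation-free root `2P / (k_L + √(k_L² + 4·k_T·P))` is used, so
  precision does not collapse as `P → 0`;
* the relation is extended to an odd function, `P = k_L·V̇ + k_T·V̇·|V̇|`,
  and the inverse maps negative pressures to negative flows.  Transient
  sub-atmospheric pharyngeal pressures during vigorous inspiration then
  invert without a domain error, and the inverse stays total, continuous,
  and exact also in the `k_T = 0` laminar limit.

A property test sweeps random admissible coefficient pairs and flows with
`|P| ≤ 50 cmH2O` and requires round-trip error below `1e-10` L/s.

## From monitored signals to tidal volumes

`compensate()` applies the inversion to every pressure sample, subtracts
the leak flow from the monitored tube flow, segments breaths, and
integrates.  Breath segmentation is deliberately simple (the method itself
puts no constraint on it):

* detection: maximal runs where a lightly smoothed copy of V̇RES (moving
  average, 50 ms) exceeds `θ = max(0.02·max|V̇RES|, 0.005 L/s)` for at
  least 0.1 s.  The absolute floor keeps noise-only records empty; the
  smoothing exists only to make the threshold crossing robust;
* delimitation: each run is widened outward to the surrounding zero
  crossings of the raw flow.  Respiratory flow is zero at the start of
  inspiration and at the start of expiration, so the widened window covers
  the whole positive lobe.  Without the widening, the threshold alone
  would truncate about 4% of a 1 L/min half-sine inspiration — more than
  the method's own error;
* integration: trapezoidal, at the native sample rate (breathing at
  ≤ 2 Hz is heavily oversampled at 100 Hz; no resampling).  The
  expiratory volume (negative lobe over the rest of the breath) is
  computed alongside but the headline quantity is inspiratory V_TID.

## The simulated bench

`simulate_npv()` integrates the network at `dt = 1 ms` and emits waveforms
decimated to 100 Hz.  At every step the node pressure solves a scalar
nonlinear equation (the Kirchhoff residual is strictly decreasing in
`P_PH`, so the solution is unique); a compiled safeguarded-Newton stepper
does this, with residuals below `1e-12` L/s, and a semi-implicit Euler
update advances the single state variable — the lung volume — in mandatory
mode.  The patient time constants used here (`r_p·c_p ≥ 0.1 s`) make 1 ms
stepping comfortably stable.  The same physics is exposed sample-by-sample
as `solve_pharyngeal_node()` (pure R root finding), and the two
implementations are cross-checked against each other and against a dense
grid-search oracle in the tests.

Mandatory records begin after five discarded warm-up breaths so that the
lung volume has reached its cycling steady state; a cold start from an
empty lung produces volume-stacking transients whose positive flow lobes
span several pump cycles, which no real recording session would include.

### Tube and leak fixtures

The three leak channels (small/medium/large) use measured bench
coefficients: (11.88, 66.88), (6.12, 32.71), (3.66, 17.34) in
cmH2O·s/L and cmH2O·s²/L².  NPT coefficients per tube size are synthetic
fixtures, not measurements: both terms scale as `d⁻⁴` (Poiseuille laminar,
orifice turbulent) times an effective length — about 30–34 cm for adult
tubes, trimmed toward the naris–pharynx insertion depth (~12 cm) for the
3.0 mm neonatal tube — and a curvature factor for the bent tube, scaled so
that the 4.0 mm tube dominates the leak resistances at paediatric bias
flow.  That is the regime in which the spontaneous (P_PH, V̇NPT)
trajectory collapses to a segment: the tube-plus-valve path is so much
stiffer than the leak that the breath is supplied almost entirely by leak
flow modulation.  Mandatory breaths instead open the trajectory into a
clockwise hysteresis loop, because the elastic patient load delays V̇NPT
relative to P_PH.  Both behaviours are asserted quantitatively in the
tests (standardised minor/major axis ratio below 0.1; negative shoelace
area).

### Noise and variability

Three stochastic layers, all seeded through a single integer:

* sensor noise: additive i.i.d. Gaussian on the *emitted* pressure and
  tube-flow channels only (defaults 0.05 cmH2O ≈ 0.2% of a ±25.4 cmH2O
  transducer span, and 0.002 L/s).  Ground-truth channels stay clean;
* per-breath amplitude jitter (`breath_cv`, default 0.8%): the delivery
  reproducibility of a mechanical breathing simulator, which reports a
  volume CV of about 0.8% even leak-free;
* per-measurement amplitude drift (`sample_cv`, default 2%,
  `run_validation()`): bench validation tables report sample-to-sample
  standard deviations of 1–3% of the nominal volume even though each
  sample is already a long average — slow drift between repeated
  measurements, not sensor noise.  Both arms of a comparison observe the
  same true breaths, so this drift is common mode: it widens the pooled
  variance estimate without separating the arms, which is precisely why
  bench comparisons of this design yield |t| well below the critical
  value.

## The validation experiment

`run_validation()` crosses nominal volumes (10/50/100 mL paediatric with
3.0/4.0/5.0 mm tubes at 16 L/min bias; 200/300/400 mL adult with
7.0/8.0/9.0 mm tubes at 32 L/min) with the three leak sizes, for
spontaneous and mandatory modes — 36 cells.  Spontaneous amplitudes follow
the half-sine closed form `A = π·V_TID/(2·TI)` with TI growing through the
protocol ranges (0.5–1 s paediatric, 1–2 s adult) and I:E = 1:2.
Mandatory pump amplitudes are calibrated numerically per cell to deliver
the nominal volume at steady state (`calibrate_pump_flow()`), with
`TE = max(2·TI, 3·r_p·c_p)` so the lung empties between breaths.  With the
synthetic tube fixtures much of the pumped flow shunts through the valve,
so the calibrated amplitudes exceed what a bench with less resistive
tubing would need; the nominal volume, not the pump setting, is the
controlled condition.

Each cell simulates 36 independent samples of 50 breaths (a desk-scale
version of 36 samples of 1000 breaths).  The *computed* arm runs
`compensate()` on the noisy monitored channels; the *measured* arm plays
the gold-standard tracheal flow sensor, reading the clean respiratory flow
through the same sensor-noise model and identical segmentation.  Arms are
compared with the pooled two-sample t test at `alpha = 0.01`:
`df = 2·36 − 2 = 70` and `t* = 2.648`.  The pooled variant is the default
because 70 degrees of freedom corresponds to the combined-variance
two-sample form (a paired test on 36 pairs would have 35); the paired
variant is implemented as well.  `null_rejection_rate()` verifies the
test's size: both arms drawn from the same generative model (drift ×
jitter × exact linear propagation of sensor noise through the fixed
trapezoidal windows) reject in about 1% of 1000 replicates.

Problem sizes throughout (36 cells × 36 × 50 breaths for the validation,
6 breaths per cell for the noise-free sweeps, 10⁴ round-trip triples, 10³
null replicates) are the package's chosen desk-scale defaults; all are
configurable.

## Known limitations

* **Low-CPAP curvature bias.**  The inversion is concave in pressure, so
  zero-mean pressure noise biases the estimated leak flow slightly low and
  the computed tidal volume slightly high — by `|f''(P)|·σ²/2` per sample,
  which is negligible at adult operating pressures but grows as the
  operating point slides down the curve.  The harshest cell (10 mL through
  a 3.0 mm tube with the large leak, pharyngeal pressure well below
  1 cmH2O) shows the grid's largest t statistics, approaching but not
  exceeding the critical value.  A bench running at higher CPAP, or a
  quieter pressure transducer, moves this bias down quadratically.
* **What the simulator does not emulate.**  The valve is linear (only its
  set point is known from the protocol); tube and leak coefficients are
  taken constant across the breath (the quasi-stationary assumption of the
  method itself); patient mechanics are linear; there is no gas-composition
  dependence of the coefficients, no tube-wall compliance, inertance or
  gas compressibility, and no cardiogenic or secretion artefacts.  Passing
  the validation grid therefore shows the algorithm is an accurate inverse
  of the stated physics under realistic noise — not that a clinical
  recording obeys that physics.
* **Segmentation is an artefact choice.**  The method prescribes only
  "integrate V̇RES over the inspiratory time"; thresholds, smoothing and
  zero-crossing delimitation are this package's defaults and are applied
  identically to both arms of every comparison.
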