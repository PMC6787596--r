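---
title: "Models and methods behind openspiro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind openspiro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openspiro)
```

`openspiro` is a software model of a dual-range pneumotachograph spirometer
with electrochemical breath-gas sensing, together with the analysis and
benchmarking pipeline such a device needs. This vignette records the models,
the tunable parameters, and the design decisions taken where the design was
genuinely open.

## 1. Device model

### Pressure channels

Flow through a fixed airflow obstruction produces a pressure drop that is,
for an orifice-plate geometry, quadratic in flow:

$$\Delta P = k\,Q^2\,\operatorname{sign}(Q).$$

The true pressure--flow characteristic of any particular obstruction is an
empirical curve; the quadratic law is the standard engineering idealisation
and is what `flow_to_pressure()` implements. Each of the two piezoresistive
bridges is linear in pressure, \(V = V_0 + s\,\Delta P\), clipped to the ADC
input range and quantized.

Per channel, `k` is normalised so that the channel's full-scale flow maps to
full ADC scale: the high-range sensor A covers 50--900 L/min and the
low-range sensor B 15--100 L/min, so in the default profile
\(k_A = 1/15^2\) and \(k_B = 0.36\) (pressure units per (L/s)²) with
\(V_0 = 0.2\) V and \(s = 4.8\) V per unit pressure. The ADC is 10 bit over
0--5 V, the resolution class of the microcontrollers such open devices are
built on; both the bit depth and the 100 Hz default sampling rate (minimum
50 Hz) are configurable in `sensor_calibration()`.

The inverse map is
\(Q = \sqrt{\max((V - V_0)/s,\,0)/k}\). Voltages below the offset are
clamped to zero flow: only forced exhalation is analysed, so negative
(inspiratory) pressure carries no information the pipeline uses. Samples
outside \([0, V_\mathrm{ref}]\) are clamped and *flagged* rather than
raised as errors, so a streamed trace survives isolated glitches.

### Dual-range fusion

Below the 50--100 L/min overlap band the low-range sensor B estimate is
used, above it sensor A; inside the band the two estimates are linearly
cross-faded, \(w = (Q_\mathrm{ref} - 50)/(100 - 50)\) applied as
\((1-w)B + wA\). The blend reference \(Q_\mathrm{ref}\) is sensor A's
estimate (overridable), because A is valid across the whole high range
while B saturates above 100 L/min — steering the weight from B would feed
the blend a saturated signal exactly where the hand-over matters.

### Gas channels

The electrochemical cell current is proportional to analyte concentration
and the potentiostat + transimpedance amplifier convert it linearly to a
voltage, so the whole chain is lumped into one volts-per-ppm sensitivity
over a baseline: \(C = (V - V_0)/s\), clamped at zero. No attempt is made
to simulate the electronics at circuit level. Default sensitivities place
the physiologic ranges comfortably on the ADC scale, and the detection
floors (0.03 ppm NO, 2 ppm CO) match the lower ends of the physiologic
ranges the sensors are calibrated to resolve. Samples below the floor are
flagged but retained.

## 2. The maneuver waveform

A forced expiration is modelled as a linear rise from zero to PEF over
`rise_time`, followed by a generalized exponential decay

$$Q(t) = \mathrm{PEF}\, e^{-((t - t_r)/\tau)^{\beta}},$$

truncated at `fet_total`. The family was chosen because it reproduces the
described loop morphology with two interpretable constants: \(\beta \ge 1\)
gives the brisk, near-exponential emptying of a healthy lung and
\(\beta < 1\) the scooped, long-tailed decay of obstruction.

Both \(\tau\) and \(\beta\) are solved numerically (Nelder--Mead on log
parameters, restarted once, `decay_shape` as the shape initialisation) so
that the waveform's closed-form integrals hit the requested FEV1 over the
first second and FVC over the whole maneuver, each within 0.5 % (the
residual check raises a named `infeasible` error otherwise). The integrals
reduce to regularized incomplete gamma functions,
\(\int_0^T e^{-(u/\tau)^\beta} du = \tau\,\Gamma(1{+}1/\beta)\,
P(1/\beta, (T/\tau)^\beta)\), so the solve is fast and the achieved metrics
returned as ground truth are exact, not quadrature estimates. Infeasible
requests (e.g. `fev1_true == fvc_true`, which no smooth positive decay can
satisfy, or an FEV1 exceeding what PEF can deliver in one second) are
rejected up front with the violated constraint named.

One consequence of solving *both* constants is that the requested
FEV1/FVC ratio, not `decay_shape` itself, ultimately pins the decay
concavity; `decay_shape` selects the branch the solver converges to. With
one free constant the two integral constraints could not be met
simultaneously.

Default `rise_time` is 0.05 s, a typical time-to-PEF; it also keeps the
offset between the generator's FEV1 definition (timed from waveform start)
and the analyzer's (timed from the back-extrapolated t₀ = `rise_time`/2 for
a linear rise) well inside the recovery tolerance.

### Phenotype presets

| preset | FEV1 (L) | FVC (L) | PEF (L/s) | shape init | FET (s) |
|---|---|---|---|---|---|
| healthy | 3.74 | 4.42 | 8.5 | 1.2 | 6.5 |
| asthma | 2.37 | 3.02 | 6.0 | 0.9 | 7 |
| COPD | 1.06 | 2.05 | 3.2 | 0.6 | 10 |

FEV1/FVC anchor the cohort group means; PEF and shape are chosen for the
characteristic loop geometry. FET values exceed the 6-s protocol minimum by
a margin because the analyzer times FET from the corrected t₀; COPD gets
10 s because obstructed exhalation genuinely takes that long to plateau —
at 8 s the trailing 1-s volume increments are still above the 0.025 L
plateau threshold.

## 3. Sessions and cohorts

A session concatenates: 60 s of tidal breathing (the gas-quantification
window), 5 s of rest before the device signals, then the forced maneuvers,
each preceded by a 2-s deep inhalation and separated by 8 s of recovery
breathing. Tidal breathing is a 0.25 Hz sinusoid with 0.5 L tidal volume;
no waveform for it is prescribed anywhere, and nothing downstream depends
on its shape. Inter-maneuver timing is likewise an invented default,
documented here and configurable. All segments are annotated in the trace,
and the whole session is a deterministic function of `rng_seed`.

Condition choices, made once and not revisited:

* **Within-subject maneuver effort**: one multiplicative lognormal factor
  per maneuver, SD 2 %, applied to the whole waveform. This makes simulated
  triplets usually — not always — pass the 0.150 L repeatability rule,
  matching the field observation that most but not all real sessions do.
* **Pressure-channel noise**: 0.8 mV SD, sub-LSB of the 10-bit ADC,
  representative of a hardware-filtered bridge. Sub-LSB matters: noise well
  below the quantization step leaves the rest-window codes stable, so
  offset estimation and near-zero-flow integration stay clean, as they do
  in the physical device after its analog filtering.
* **Gas dynamics**: first-order equilibration toward the true concentration
  with a 2-s time constant after the subject engages the mouthpiece, plus a
  per-session random linear baseline drift (slope SD 0.2 mV/s) and white
  noise. Electrochemical cells do drift and equilibrate slowly; magnitudes
  are configurable.
* **Cohort draws**: per group, FVC is lognormal with the group's mean and
  SD (exact first two moments, positive support); the FEV1/FVC ratio is
  normal around the group mean ratio (SD 0.06, clamped to [0.25, 0.92])
  and FEV1 is the product. Group anchors: healthy 3.74/4.42 L, asthma
  2.37/3.02 L, COPD 1.06/2.05 L. PEF scales as 2.2·FEV1 + 0.5.
* **Paired devices**: maneuver effort factors are drawn per subject ×
  maneuver index and shared across the two virtual devices, so maneuver
  *i* pairs with maneuver *i*; each device gets independent sensor noise
  and its own physical calibration jitter (lognormal, SD 0.5 % on the
  orifice coefficients) while the analysis side only ever knows the
  nominal profile — i.e. inter-device disagreement comes from noise and
  calibration error, as it would in hardware.

What the simulator does **not** emulate: coughs, glottic closure,
variable effort within a maneuver, leak artifacts, temperature/humidity
effects, BTPS correction, or the NO-sensor cross-sensitivity failure mode
seen with some commercial cells. Passing recovery tests therefore show the
*analysis chain* is correct and the *device model* is internally
consistent; they are not evidence about artifact robustness on real
patients.

## 4. Analysis conventions

* **Zeroing**: per-channel median voltage over the annotated 5-s rest
  window, applied before inversion (median, so a stray glitch cannot drag
  the offset). Missing annotation falls back to the first 2 s with a
  warning.
* **Back-extrapolation**: t₀ is where the tangent to the volume--time curve
  at maximal flow crosses zero volume; BEV is the measured volume already
  expired at t₀. BEV acceptability uses max(0.150 L, 5 % FVC) — this is
  *extended grading*: the repeatability rule is the explicitly stated
  criterion, the BEV and FET flags are the conventional additions.
* **End of test**: earliest sample after which every trailing 1-s window
  accumulates < 0.025 L. **FVC is read as the plateau level** — the
  cumulative volume at the end of the maneuver segment — not the volume at
  the quiet-window start: an obstructive decay keeps delivering sub-
  threshold volume for seconds after the plateau criterion first fires,
  and discarding that tail would bias FVC low by up to ~2 % exactly where
  accuracy matters most. The two readings can differ by at most the
  threshold per trailing second.
* **FET** is timed from t₀ to the end of the maneuver segment (the end of
  detectable exhalation), with the plateau time reported separately
  (`plateau_time`). Timing FET to the plateau start would fail the ≥ 6 s
  requirement for any waveform whose terminal flow is below the flow
  resolution, which is physiologically wrong.
* **FEV1 interpolation**: linear between samples at t₀ and t₀ + 1 s; at
  100 Hz the induced error is below 0.5 mL for physiologic flows.
* **Repeatability comparison**: two largest values sorted descending,
  difference compared against 0.150 L with a 1 ns-scale epsilon so a
  difference that equals the limit in exact arithmetic is not failed by
  binary rounding; equal values trivially pass. Best FEV1 and best FVC are
  taken independently (possibly different maneuvers); the reported ratio
  comes from the maneuver with the largest FEV1 + FVC sum.
* **Percent predicted** is pure plumbing: a pluggable registry maps a
  demographic stratum to a prediction function. No reference equations
  ship with the package.

## 5. Gas quantification

The default summary is the windowed **mean** (with SD) over the tidal
window after discarding the first 10 s for equilibration; end-tidal peak
extraction exists in the literature but is not the default here and is
unvalidated in this package. NO is additionally reported in ppb
(exactly 1000 × ppm). Readings are marked unreliable when the protocol
order is violated (any gas window after a forced maneuver — spirometry
transiently depresses exhaled NO) or when most samples sit below the
detection floor; unreliable readings are excluded from pooled summaries
unless explicitly included.

`calibrate_gas_sensor()` fits the linear response by least squares and
rejects fits with R² < 0.99: the transduction model *assumes* linearity,
so a curved response is a sensor fault, not a fit to tolerate. This is
also the diagnostic that would catch a miscalibrated or cross-sensitive
NO cell.

## 6. Agreement statistics

Pearson r uses the standard product-moment estimator with a two-sided
t-transform p-value. Bland--Altman reports bias ± 1.96·SD of the paired
differences (SD with n−1; the 1.96 normal multiplier is the conventional
reporting choice and is configurable, not a t quantile). The two-factor
ANOVA (device × health state, with interaction) uses type-II sums of
squares since cohort cells are unbalanced; with a single-level second
factor it degenerates to one-way ANOVA, where the two-level F equals the
squared two-sample t. Per-maneuver pairing is the default ANOVA mode;
per-subject means are available (`anova_mode = "per_subject"`) because
which of the two a given study used is often unstated.

## 7. Numerical notes and problem sizes

Waveform solving: two Nelder--Mead passes at `reltol` 1e-15; residuals
above 0.5 % are treated as infeasibility, not silently accepted. Volume
integration is the cumulative trapezoid (exact for the piecewise-linear
parts of the waveform). Ties in `which.max` (PEF) resolve to the first
sample, i.e. the rise--decay junction. Degenerate inputs — all-zero
traces, zero-variance correlations, empty ANOVA cells, fewer than two
maneuvers, sub-10-s gas windows — return explicit statuses or named
errors rather than NaN.

The shipped test suite and the acceptance script use problem sizes chosen
to make sampling error negligible relative to the tolerances while keeping
a full run in the minutes range on one core: 200 maneuvers for the
recovery sweep (120 in the script), 10,000 triplets against the grading
oracle, 500 null replicates for the ANOVA type-I check, 100 sessions for
gas recovery, and a 43-subject × 3-maneuver × 2-device benchmark cohort —
the size at which such devices are typically benchmarked clinically. The
benchmark's near-perfect agreement (r ≈ 0.9999, LoA half-width ≈ 0.02 L)
is a *designed property of the simulator defaults* (shared effort factors,
small calibration jitter); it is a consistency check of the pipeline, not
a reproduction of any clinical dataset.

## 8. Known limitations

* The orifice coefficient values are synthetic: the real obstruction's
  pressure--flow curve is not published, so absolute pressures are in
  normalised units (the flow scale, which is what matters downstream, is
  exact by construction).
* The NO chemistry is a generic linear cell; the package models no
  specific failure mode, only the calibration diagnostics that would
  reveal one.
* No inspiratory metrics, no bronchodilator-response logic, no pediatric
  strata, no BTPS correction.
* The flow-volume "total lung capacity" reading sometimes quoted for the
  loop's x-axis endpoint is, physiologically, the FVC; the package reports
  FVC and never labels it TLC.
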