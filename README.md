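# openspiro

A virtual mobile spirometer and exhaled-breath monitor, end to end in R.

Portable spirometers that also read exhaled breath gases promise cheap,
frequent lung-function monitoring for people with asthma and COPD. One
open-architecture design infers flow from the pressure drop across a fixed
airflow obstruction using **two differential-pressure sensors** covering
complementary ranges (high flow 50–900 L/min, low flow 15–100 L/min), and
quantifies exhaled **nitric oxide** and **carbon monoxide** with
electrochemical cells behind a potentiostat and transimpedance amplifier.
`openspiro` models that whole instrument in software — transduction,
protocol, analysis and benchmarking — so the signal chain can be studied,
stress-tested and extended without hardware.

The package is aimed at respiratory-device and biomedical-signal people who
want a fully controllable test bench: every simulated session carries its
exact ground truth, so recovery error of the analysis pipeline is always
measurable.

## What it computes

**Transduction.** The obstruction obeys the quadratic orifice law
ΔP = k·Q², the piezoresistive bridge is linear in pressure
(V = V₀ + s·ΔP), and a 10-bit ADC quantizes over 0–5 V. The inverse map is
Q = √(max((V − V₀)/s, 0)/k); the two single-sensor estimates are fused with
a linear cross-fade over the 50–100 L/min overlap band.

**Spirometry.** Volume is the cumulative trapezoidal integral of flow.
Time zero is corrected by back-extrapolation (tangent to the volume–time
curve at peak flow), giving the back-extrapolated volume BEV. Then

- FEV1 = V(t₀+1 s) − V(t₀) — volume delivered in the first second,
- FVC — total (plateau) exhaled volume,
- PEF — maximum flow, FET — expiratory time from t₀,

with per-maneuver acceptability flags and the session repeatability rule:
the two largest FEV1 values (and the two largest FVC values) must agree
within 0.150 L.

**Breath gases.** Linear sensor inversion C = (V − V₀)/s, a windowed mean
over the 60-s tidal-breathing phase after discarding a 10-s equilibration
span, detection-floor flags (0.03 ppm NO, 2 ppm CO), physiologic-range
checks (NO 0.03–0.13 ppm, CO 2–7 ppm), least-squares sensor calibration
with a linearity gate, and a protocol-order check (gas must be quantified
*before* forced maneuvers, which depress exhaled NO).

**Agreement.** Device-versus-device benchmarking: Pearson r, Bland–Altman
bias with 95 % limits of agreement (bias ± 1.96 SD of the paired
differences), two-factor (device × health state) ANOVA with type-II sums
of squares, and repeated-reading correlations.

**Simulator.** Forced maneuvers are a linear rise to PEF followed by a
generalized-exponential decay whose scale and shape are solved numerically
so the waveform's integrals hit the requested FEV1 and FVC; presets give
healthy, asthmatic and COPD (scooped-loop) phenotypes anchored to typical
group means. Sessions add tidal breathing, rest, recovery segments, gas
equilibration/drift, sensor noise and ADC quantization — all deterministic
under a seed.

## Worked example

```r
library(openspiro)

sc  <- session_script(subject_group = "asthma", rng_seed = 42)
ses <- make_session(sc)                 # raw 4-channel voltage trace
res <- analyze_session(ses$trace)       # reconstruct + metrics + grading

res$maneuvers[[1]]
#> <spirometry_metrics> FEV1 2.417 L | FVC 3.066 L | ratio 0.788 |
#>   PEF 6.17 L/s | FET 6.97 s | BEV 0.040 L
res$report
#> <acceptability_report> repeatable FEV1: TRUE | repeatable FVC: TRUE |
#>   acceptable maneuvers: 3
#>   best FEV1 2.417 L, best FVC 3.066 L, ratio 0.788

analyze_gas(ses$trace)$co
#> <gas_reading CO> mean 3.06 ppm (sd 0.01118 ppm, n = 5001),
#>   in physiologic range, 0% below floor
```

The asthma preset targets FEV1 2.37 L / FVC 3.02 L; this session's first
maneuver drew a slightly high effort factor, and the pipeline recovers its
ground truth to well under 1 %. The CO channel was simulated at 3.04 ppm
true concentration; the windowed mean lands within the session's drift
envelope. A paired-device benchmark is one call:

```r
bm <- benchmark_cohort(make_cohort(20, seed = 1))
bm$fev1
#> <agreement_result FEV1> n = 60 pairs (0 excluded)
#>   Pearson r = 1.0000 (p = 1.01e-126)
#>   Bland-Altman bias -0.0003, 95% LoA [-0.0186, 0.0179]
#>   device effect: F = 0.000, p = 0.998
```

## Scope notes

Only forced *exhalation* is analysed (inhalation is clamped to zero during
reconstruction). Percent-predicted values are computed through a pluggable
reference-equation registry; the package deliberately ships no reference
equations of its own. See the methods vignette
(`vignettes/breath-device-methods.Rmd`) for the model, parameter and
design-decision details.
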