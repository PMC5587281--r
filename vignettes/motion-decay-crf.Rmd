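---
title: "Estimating cardiorespiratory fitness from squat-test motion decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cardiorespiratory fitness from squat-test motion decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squatfit)
library(dplyr)
```

## The problem

Peak oxygen uptake (V̇O2peak) is the standard measure of cardiorespiratory
fitness, but measuring it directly requires a maximal exercise test with a
metabolic cart. Submaximal field tests usually estimate it from the heart-rate
response to a standardized workload — an approach that fails in patients on
β-blockers, whose heart-rate response is pharmacologically blunted. Coronary
artery disease (CAD) patients, for whom fitness tracking matters most, are
mostly in that group.

`squatfit` implements an alternative that needs no heart-rate data at all:
a 45-second squat test at a fixed metronome tempo (80 bpm, one beat down, one
beat up, i.e. a repetition frequency of 2/3 Hz), recorded with a single
tri-axial accelerometer. The premise is physiological: an unfit subject
fatigues during the test and their movement pattern deteriorates — amplitude
shrinks, timing drifts — while a fit subject squats the 45 seconds with an
almost unchanged pattern. The package quantifies that *motion decay* and feeds
it, together with basic subject characteristics (weight, age, sex), into
linear models of absolute V̇O2peak in L/min.

## The motion-decay feature

From a harmonized recording (20 Hz, ±2 g; see below) the pipeline computes:

1. **Magnitude.** The per-sample Euclidean norm
   $\mathrm{Magn}[i] = \sqrt{x_i^2 + y_i^2 + z_i^2}$ collapses the three axes
   into a series that is robust to sensor orientation.
2. **Windows.** Two 150-sample (7.5 s) windows are cut from the magnitude:
   `MagnFP` at samples [200, 350) — 10 s into the test, after the subject has
   settled into the tempo — and `MagnSP` at [650, 800), near the end.
3. **Preprocessing.** Each window is de-meaned (removing the 1 g gravity
   component and slow baseline) and low-pass filtered at 4 Hz with a
   zero-phase 4th-order Butterworth filter. Voluntary squatting at 2/3 Hz has
   little physiological content above 4 Hz; what is removed is sensor noise.
4. **Cross-correlation.** The unnormalized cross-correlation
   $R_{FS}[n] = \sum_m \mathrm{MagnFP}[m]\,\mathrm{MagnSP}[n+m]$ is evaluated
   at all 299 overlapping lags (zero-padded), and the feature is its signed
   maximum,
   $R_{FSmax} = \max_n R_{FS}[n]$.

$R_{FSmax}$ is large when the late window still looks like the early one
(well-preserved pattern, high fitness) and small when amplitude has decayed or
the waveform has changed. Three conventions deserve emphasis because they are
easy to get wrong:

* **Unnormalized.** Dividing by the window energies would discard the
  amplitude information that carries most of the fitness signal; the feature
  scale (units g²·samples, typical values ≈ 4–20) only makes sense
  unnormalized. `compute_rfsmax(rec, normalize = TRUE)` exposes the
  energy-normalized variant in [−1, 1] as a clearly separate feature.
* **Signed maximum.** The feature measures similarity; an anti-correlated
  window is not similar, so the maximum is not taken over absolute values.
* **Zero-phase filtering.** A causal filter would add group delay to both
  windows; any asymmetry in that delay would shift the correlation maximum.
  The forward–backward pass has exactly zero phase.

### Window index convention

Verbal descriptions of the windows ("from the 200th to the 350th sample")
span 151 samples if both ends are inclusive, yet the windows are defined as
150 samples each. The package resolves this in favour of the stated length
with 0-based half-open intervals [200, 350) and [650, 800). The placement of
a single boundary sample has a negligible effect on a 150-sample correlation
maximum; the length is what must be exact.

## Harmonization

Two device conventions are supported out of the box: a belt-worn monitor
sampling at 20 Hz with a ±2 g range, and a wrist-worn monitor at 16 Hz and
±8 g. All recordings are harmonized to 20 Hz / ±2 g before feature
extraction so that the feature scale is comparable across devices:

* **Resampling** uses FFT spectral zero-padding on an odd-reflection
  (point-symmetric) extension of the signal. The extension keeps value and
  slope continuous at both ends; constants are preserved to machine precision
  and a band-limited 1 Hz tone resampled from 16 to 20 Hz agrees with the
  analytic sinusoid to ~2 × 10⁻⁶ away from the edges. The method accepts any
  rational rate ratio (continued-fraction approximation, denominator ≤ 1000).
  A windowed-sinc polyphase FIR was considered and rejected: at practical
  filter lengths its per-branch DC gain ripple perturbs constants at the
  10⁻⁴ level, visible in exactly the saturation-adjacent regime we care
  about.
* **Saturation to ±2 g happens after resampling.** Clipping first would
  create spectral content the interpolator must not see.
* A recording already at 20 Hz and inside ±2 g is returned unchanged, sample
  for sample, which makes `harmonize()` exactly idempotent.

Downstream, the feature is insensitive to this step: for band-limited
synthetic signals, extracting $R_{FSmax}$ through the 16 Hz route changes it
by well under 2% relative to the native 20 Hz computation.

### Filter edge handling

Windows are padded by 30 samples of *mirror* (even) reflection before the
forward–backward pass. Because the windows are de-meaned first, mirror
padding adds no DC at the joins. The more common odd-reflection padding
(as in MATLAB's and SciPy's `filtfilt`) injects a DC offset of twice the edge
value into the pads; a low-pass filter passes that offset straight into the
window edges. On a unit 8 Hz tone ending far from zero, odd-reflection
`filtfilt` leaves an edge excursion of ≈ 0.59, mirror padding ≈ 0.16 — both
are edge transients, not frequency response. Tests therefore measure the
filter's gain by least-squares projection onto the quadrature pair at the
probe frequency over the central 100 samples, which reproduces the analytic
double-pass Butterworth magnitude (1 Hz: 0.99998; 8 Hz: 0.0039).

## The prediction models

Three published coefficient sets ship with the package (`vo2_model()`), all
linear in their predictors with sex coded female = 0, male = 1:

| model | derivation group | predictors |
|---|---|---|
| `1a` | 30 healthy adults | weight, age, sex, R_FSmax |
| `1b` | 17 healthy adults with relative fitness < 40 ml/min/kg | weight, age, sex, R_FSmax |
| `2` | 18 male CAD patients | weight, age, R_FSmax |

Model 2 has no sex term because its derivation group was all male. The sex
coding was sanity-checked against the coefficient signs: males have higher
absolute V̇O2peak at equal weight/age/feature values, and the positive sex
coefficients (0.674, 0.18 L/min) are only consistent with male = 1.

`fit_vo2()` refits any predictor subset de novo by ordinary least squares
(through `stats::lm`), reporting per-coefficient SE, t and two-sided p, the
Pearson correlation r between fitted and measured values, adjusted r², and
the in-sample RMSE defined as the root *mean* squared residual (denominator
n, not n − p − 1).

**Forced entry versus stepwise.** The reference coefficient sets contain
terms with p-values up to 0.512, which no conventional p-to-enter forward
selection would admit. Reproducing them therefore uses forced-entry OLS with
the fixed predictor lists above. A configurable `stepwise_forward()` (entry
at the smallest candidate p below `p_enter`, ties broken by candidate order,
deterministic) is provided as a separate operation for users who want actual
selection.

## Validation statistics

`loocv_vo2()` implements leave-one-subject-out cross-validation with a
*fixed* predictor set per fold — no per-fold reselection, since the object
under validation is one coefficient set. It reports:

* `rmse_cv` (L/min) and `rmse_cv_pct` — the latter relative to the analyzed
  group's mean measured V̇O2peak;
* `r_cv`, the Pearson correlation between held-out predictions and
  measurements. This is deliberately distinct from the in-sample `r` of the
  fit: both are reported, and `rmse_cv ≥ rmse` essentially always holds;
* Bland–Altman agreement: differences are `predicted − measured`, bias is
  their mean, and the limits of agreement are bias ± 1.96 × sample SD.
  **Bias and LoA are computed from the cross-validated predictions**, a
  deliberate choice: the in-sample bias of any OLS fit with intercept is zero
  by construction, so an in-sample Bland–Altman would be vacuous. Reference
  analyses that print small non-zero biases are only reproducible under the
  cross-validated convention.

`partial_correlations()` reports, per predictor, the correlation between
V̇O2peak and that predictor after regressing both on the remaining terms
(residual-on-residual). `fitness_category()` bins relative fitness
(1000 · V̇O2peak / weight, ml/min/kg) into [20, 30), [30, 40) and [40, 50)
with lower-inclusive edges; out-of-range subjects go to the nearest edge bin
with a warning flag rather than erroring, because single atypical subjects
should not kill a cohort report. `rmse_by_category()` recomputes the held-out
RMSE within each bin, as absolute L/min and as a percentage of that bin's own
mean measured V̇O2peak; empty bins are absent from the output, not zero.

`run_reproduction()` chains all of the above for the three models, applying
the normal-to-low filter for model 1b and the males-only CAD filter for
model 2, and serializes to fixed-precision text and JSON (coefficients at 5
decimals, metrics at 3) so that repeated runs are byte-identical. Note that
regenerating the published per-subject statistics requires the original
study's subject-level table, which is not redistributable with the package;
on any schema-compatible table the same report is produced for that cohort.

## The synthetic generators

Because subject-level study data cannot ship with the package, every stage is
testable against two seeded generators.

**`simulate_squat_signal()`** produces a quasi-periodic squat waveform: a
fundamental at 2/3 Hz plus two harmonics with fixed relative amplitudes
(1, 0.4, 0.15) — enough spectral structure below 4 Hz that the filtering
stage is meaningfully exercised — a 1 g gravity offset on the vertical axis,
smaller transverse components (35% and 25% of the vertical amplitude), and
white Gaussian sensor noise (default SD 0.02 g, a realistic MEMS noise floor
at 20 Hz). Two fatigue knobs map onto the two ways real patterns decay:
`amplitude_decay` scales the envelope by `1 − decay · t/duration`, and
`tempo_drift` lengthens the instantaneous period by `drift · t/duration`
(phase obtained by exact integration, not by frequency modulation artifacts).
Defaults: 45 s, 20 Hz, base amplitude 0.5 g (wrist-typical; belt-worn signals
run at roughly half that).

**`simulate_cohort()`** draws subject tables. Characteristics follow
group-typical distributions (healthy: weight 77.4 ± 12 kg, age
31.3 ± 7.8 yr, 60% male; CAD: 93.7 ± 11.7 kg, 56.6 ± 7.4 yr, all male) and
V̇O2peak is generated from the matching published coefficient set plus
Gaussian noise at that model's in-sample residual scale (0.437 / 0.205
L/min). The feature comes either from a truncated normal at the
group-typical scale (healthy 18.6 ± 7.7, CAD 4.6 ± 1.8; fast, exactly linear
— used for estimator-property tests) or, with `rfsmax_from = "signal"`, by
actually simulating one squat recording per subject with fatigue decay linked
to a latent relative fitness and running `compute_rfsmax()` (slower; used for
end-to-end pipeline tests). The link is
`decay = clamp(0.75 − 0.015 · rel_fitness, 0, 0.95)`, calibrated once so
that simulated wrist and belt cohorts land on the feature ranges quoted
above; only its direction (fitter → less decay) is physiologically asserted.

**What the generators do not emulate** — and therefore what passing tests do
*not* establish about real data: no biomechanics (a squat is not three
harmonics; inter-repetition variability, pauses and posture adjustments are
absent), no non-stationary or heavy-tailed sensor artifacts, no timestamp
gaps, no device mis-wearing, and an exactly linear V̇O2peak structure that
real cohorts only approximate. The synthetic results validate the *software*
— estimator correctness, convention consistency, pipeline monotonicity — not
the clinical accuracy of the published models, which only subject-level study
data can.

All randomness flows from a single per-call `seed`; the global RNG state is
saved and restored, so generators never perturb a user's session.

## Numerical choices and degenerate inputs

* Cross-correlation is computed by FFT (`stats::convolve`); the test suite
  pins it to a brute-force double-loop oracle at < 10⁻⁹ relative error over
  hundreds of random window pairs, and the two impulse conventions fix the
  lag sign.
* Rank-deficient designs (e.g. a constant sex column after filtering to an
  all-male group) raise a typed singularity error, in `loocv_vo2()` naming
  the offending fold; `lm`'s silent NA coefficients are never propagated.
* Stepwise ties are broken by candidate order; an empty selection returns the
  intercept-only fit rather than erroring.
* Partial correlations with (near-)constant residuals raise a typed
  degenerate-result error instead of returning NaN.
* Recordings shorter than 800 samples at 20 Hz (40 s) cannot host the second
  window and raise an insufficient-duration error reporting required versus
  actual length.

## Problem sizes used in the validation suite

The shipped tests run the cross-correlation oracle on 200 random window
pairs, the decay grid {0, 0.2, 0.4, 0.6} at 50 seeds per level, tempo-drift
grids at 50 seeds, coefficient recovery on 100 cohorts of n = 200,
cross-validation dominance on 100 cohorts of n = 30, cohort moments at
n = 1000, and the full signal-based pipeline at n = 50 over 20 seeds. These
sizes were chosen so that Monte-Carlo margins are comfortable for the
assertions made (e.g. recovery bias is tested at < 5% per term where the
standard error of the mean estimate sits near 1–2%).

## Known limitations

* The exact reproduction of published bias/LoA figures depends on the
  cross-validated-differences convention documented above; analyses that
  computed agreement from in-sample fits would differ.
* The entry/stay criteria of the original model selection are not
  reconstructible from the published coefficient sets; `stepwise_forward()`
  is a faithful generic implementation, not a claim about how the reference
  sets were chosen.
* The feature is tempo-anchored: it assumes the test was performed at the
  80 bpm metronome protocol. Recordings at other tempos will produce valid
  numbers on the wrong scale.
* Group-difference significance tests between cohorts (sex differences,
  healthy versus CAD) are out of scope; the package models V̇O2peak only.
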