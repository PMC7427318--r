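---
title: "Methods: arousal-state analysis of retinal output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arousal-state analysis of retinal output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in
`retistate`, the assumptions behind them, the choices made where the
method left details open, and what the synthetic-data validation does and
does not establish.

## The scientific setting

Arousal — indexed by running speed and pupil size — modulates neural
activity throughout the mouse visual system. Whether that modulation is
already present in the output of the retina is tested on two kinds of
recordings: two-photon calcium imaging of retinal ganglion cell boutons
(and superior colliculus neurons), and extracellular spikes from optic
tract axons. Both are slow, drifting, autocorrelated signals, so the
analysis leans on three pillars: careful trace-level preprocessing,
model-based single-trial response estimation, and resampling nulls that
preserve temporal structure.

## Preprocessing of fluorescence triplets

Each unit contributes three traces: somatic/bouton fluorescence `F`,
surrounding-neuropil fluorescence `N`, and an activity-independent red
channel.

* **Baselines.** All slow baselines are the 8th percentile in a moving
  window of 180 s, computed exactly on truncated windows at the trace
  edges (no padding). The implementation is a sliding sorted-window
  C++ routine using R's type-7 quantile; the test suite checks it
  against a brute-force windowed percentile everywhere.
* **Neuropil factor.** With high-passed traces `F_f = F − F_0`,
  `N_f = N − N_0`, the factor `α` is the slope of a linear fit of `N_f`
  to `F_f`. "Low values of F_f" (quiescent epochs) is operationalized as
  samples below the 50th percentile of `F_f`, with one refit after
  discarding the 5% largest absolute residuals; `α` is clipped to
  [0, 1.5]. The fit is per unit per session.
* **ΔF/F.** `F_c = F − α·N`, `ΔF/F = (F_c − F_c,0) / max(1, mean F_c,0)`;
  the `max(1, ·)` guard keeps dim units from amplifying noise.
* **Red regression.** The red trace is drift-removed, median-filtered in a
  10-s window, and its least-squares projection subtracted from ΔF/F;
  a zero-variance red trace leaves the input untouched.
* **Exclusions.** Duplicate units (adjacent planes, centroids within
  5 µm, 5-sample-median-filtered traces correlated above 0.4 for somata /
  0.5 for boutons) are resolved by keeping the higher-SNR member.
  Units with suprathreshold excursions longer than 25 s are flagged; the
  detection threshold of 3 robust SDs is this package's choice, since the
  source method fixes only the duration rule. Moving medians use
  `stats::runmed`.

## Single-trial responses from slow calcium

Stimulus-triggered averages fail when calcium decay outlasts the
inter-trial interval. The response model is instead

  `ΔF/F(t) ≈ b + Σ_i s_i · k(t − t_i)`

with one 15-s kernel `k` per unit and one scaling `s_i` per trial,
alternating (i) a linear fit of `k` given `s` (trial windows superposed
additively where they overlap) and (ii) a linear fit of `s` given `k`,
starting from `s_i = 1`, until the maximum relative change of the
scalings falls below 1e-4 (at most 100 alternations). The kernel is
renormalized to unit peak magnitude after each iteration, with scalings
rescaled to preserve the product — this resolves the scale ambiguity the
alternation otherwise leaves open. Because every regressor is a shifted
copy of the same window, both normal-equation systems are built directly
from the trial-onset offsets (a banded matrix and a windowed gather); no
design matrix is formed. The trace must extend one kernel length past the
last onset so all windows are complete. Training MSE is non-increasing
across iterations and is asserted as an invariant.

**Responsiveness.** The trace is circularly shifted against the stimulus
times (shifts ≥ 30 s; 200 by default) and the model refitted per shift;
a unit is responsive when its MSE lies below the null 95% band
(one-sided p < 0.025). Overlapping kernels of adjacent trials are summed
(superposition), the natural convention for a linear model.

## Direction tuning across pupil states

Trials are labeled small/large pupil at the session median; a trial is
"small" only when strictly more than half of its non-blink samples fall
below the threshold, so a constant pupil yields all-large labels.

The tuning curve is a sum of two wrapped Gaussians with peaks 180° apart
plus an offset, parameterized by preferred direction θp, peak response P
above offset, width σ, direction selectivity DS, and offset; the
null-direction response N = P(1−DS)/(1+DS) is derived. The two Gaussian
amplitudes solve a 2×2 linear system so that f(θp) = offset + P and
f(θp+180) = offset + N hold exactly (wrap terms k ∈ −2…2). σ is bounded
below by the direction sampling interval; DS is constrained to [0, 1],
with sign flips absorbed by rotating θp 180°.

The optimizer profiles the linear parameters: for fixed (θp, σ, DS) the
per-state (offset, P ≥ 0) solve is closed-form, and a bounded
quasi-Newton search runs over the three shape parameters from four θp
starts (vector-sum estimate + 90/180/270°), ties broken toward smaller σ.
For pupil pairs, (θp, σ, DS) are shared and only (P, offset) vary per
state; for pupil × V1-inactivation quadruples only θp is shared. Units
suppressed by gratings are fitted on negated responses.

* **Tuned vs flat:** leave-one-repeat-out cross-validation compares
  held-out explained variance of the wrapped-Gaussian fit against a
  constant; untuned units use the fitted constant as their
  preferred-direction response.
* **Modulation:** `M = (L − S)/(½(L + S))` on preferred-direction
  responses (offset + P, consistent with the untuned-unit constant) and
  on tuning depth (max − min of the fitted curve on a 1° grid; tuned
  units only). Significance permutes the pupil labels (200×) and refits;
  permutation p-values always use the add-one correction, so p = 0 is
  impossible.
* **Selectivity:** DSI is the modulus of the amplitude-weighted resultant
  Σ R_k e^{iα_k}/Σ R_k (negative amplitudes clipped to zero after any
  suppression inversion); OSI doubles the angles first. Significance
  permutes directions across trials (1,000×, one-sided).

## Receptive fields from sparse noise

Responses binned at the 6-Hz frame times are regressed on indicators of
white squares (ON block) and black squares (OFF block) at each position
and stimulus lag (1–3 frames before the response for calcium; 0–1 for
spikes), plus running-speed regressors spanning −5…+5 s. The penalty is
`λ_rf(‖Δw_ON‖² + ‖Δw_OFF‖²) + λ_run‖Δ_t h‖²` with Δ the discrete spatial
Laplacian per lag and Δ_t the temporal second difference; the solve is
closed-form with an unpenalized intercept. λ pairs are chosen on a 7-point
logarithmic grid spanning six decades per axis by 10-fold cross-validation
with contiguous time blocks (guarding against temporal leakage), and the
final model is refitted on the full trace.

A field is accepted when (i) the held-out explained variance of the
stimulus component alone — computed against the response minus the fitted
running component and intercept — exceeds 0.01, (ii) a circular-shift
test on that quantity gives p < 0.05 (the same folds are reused for the
null refits), and (iii) the half-height ellipse covers less than 25% of
the stimulus area, this package's operationalization of "spatially
confined". Spatial maps are read at the lag of maximum energy; the peak
pixel is the argmax of the mean of |ON| and |OFF|; when both peak values
are negative their signs are inverted, and when they disagree in sign the
weaker is zeroed. The outline ellipse is a moment-based 2-D Gaussian fit
to the half-height region of the summed field (half-height semi-axes
√(2 ln 2)·σ) — the source method names the fit but not the algorithm.

## Resampling statistics

* **Shift test:** the null for a correlation between a neural trace and a
  behavioral trace circularly shifts the latter (≥ 30 s, 500×; the floor
  prevents near-identity shifts and is this package's choice).
  Significance follows the 2.5–97.5 percentile-interval rule; a two-sided
  add-one p-value is reported alongside, since the source method implies
  two-sidedness through the interval rule without stating a p convention.
* **Cross-correlograms** operate on drift-subtracted (8th percentile,
  180 s), 1-s-Gaussian-smoothed, z-scored signals on a 133-ms grid;
  segmented recordings are averaged per segment with shifts applied to
  the concatenation. The lag-0 value equals the Pearson correlation of
  the processed signals exactly.
* **Fisher's combined test:** χ² = −2Σ ln p over units, df = 2n.
* **Circular paired test:** differences of paired angles (period 360 or
  180) are tested for nonzero circular mean through the confidence
  interval of the mean direction (Zar's concentration-based interval),
  re-implemented from its definition; the approximate p is found by
  bisection on the confidence level.

## Spike-stream quality control

Optic-tract recordings are vulnerable to electrode drift. Spikes are
binned 100 at a time; each bin's modal ("mass") amplitude is a
kernel-density mode (Silverman bandwidth — the source states only "most
frequent"), smoothed over 3 bins; the amplitude SD comes from a
half-Gaussian fit to positive deviations; spikes below mass − k·SD
(k ∈ [5, 20], default 10) are dropped. Units whose binned mean amplitude
correlates with firing rate under the shift test are excluded. Waveform
stability between running and stationary episodes is quantified as the
Pearson correlation of concatenated mean waveforms with a 0.95 flagging
threshold — a quantification of what the source method checked by eye.
Anatomical and flicker-response selection criteria require histology and
dedicated stimuli and are carried only as metadata.

## The synthetic-session generator

The generator produces what the analysis assumes: running speed is a
rectified Ornstein–Uhlenbeck process with a 10-s correlation time; pupil
area is a 1-s-lagged, smoothed mixture of the running drive (weight =
`coupling`) and independent 20-s OU noise, so shift tests on simulated
pairs are meaningful; blinks are 0.2-s dropouts (< 2% of samples).
Gratings run 2 s with 3–6-s gray gaps, 12 equally spaced directions by
default (enough for stable wrapped-Gaussian fits); sparse noise uses
10°-edge squares at 6 Hz with 1%/1% white/black probabilities. Unit
latents superpose per-trial gains (drawn from the unit's own tuning curve
in the trial's pupil state, labeled by the same median rule the analysis
uses), an exponential calcium kernel (τ = 0.5 s, GCaMP6f-like; the source
never states a forward model), a running drive, an optional linear
receptive-field drive, and a slow drift whose amplitude is tied to the
single noise knob (0.5·noise_sd) so that noiseless synthesis is exactly
noiseless. Raw fluorescence adds a shared slow neuropil contaminant
scaled by each unit's true α, and an activity-independent red channel.
Everything is bit-reproducible under a fixed seed.

What passing tests on this generator shows: the estimators are consistent
and calibrated when the data match the model class (linear superposition,
exponential kernels, Gaussian noise, stationary contamination). What they
do not show: robustness to non-exponential indicator dynamics, saturating
or nonlinear responses, non-stationary arousal statistics, or optical
artifacts beyond a shared slow contaminant — real-data caveats the
preprocessing rules (transient-duration, drift and duplicate exclusions)
exist to mitigate.

## Numerical choices and problem sizes

* Alternating-fit tolerance 1e-4 (relative scaling change), cap 100
  alternations; shift-null refits cap at 10–20 alternations, enough for
  the MSE statistic to stabilize while keeping the observed/null
  comparison symmetric.
* Tuning optimizer: L-BFGS-B, four θp starts, finite-difference step
  1e-5, σ ∈ [direction spacing, 200°].
* Validation sizes: tuning recovery uses 100 units at 15 repeats × 12
  directions with noise SD 0.2·P; pair recovery 50 units; shift-test
  calibration 500 pairs of 1-s-smoothed white noise (20-minute traces at
  7.5 Hz, 500 shifts); responsiveness calibration 200 null AR(1) units
  and 40 high-SNR units on a 4-direction × 4-repeat schedule over a
  20-minute trace, with 119 shifts and a 10-alternation cap (119 shifts make the
  nominal level of the p < 0.025 rule exactly 3/120 = 0.025);
  neuropil recovery 100 units; receptive fields 30 units on an 8×8 grid
  at SNR 2 with fixed moderate smoothing (λ = 5).
* Trace length matters for shift-test validity, not just power: the
  surrogate correlations at nearby circular offsets are themselves
  correlated, so the percentile band is only estimated stably when the
  allowed offset range holds many offsets that are well separated on the
  signal's correlation scale. Twenty-minute traces — within the range of session durations for this
  kind of recording (5–40 min; optic-tract sessions run ~40 min) —
  satisfy this; on very short traces the empirical band is noisy and the realized level of the
  percentile rule drifts above nominal. Shift offsets are drawn without
  replacement so surrogates are distinct.
* The photoisomerization rate formula
  π·I·1500·τ(λ)·(S_pupil/S_retina)·a_c is evaluated literally; with the
  published parameter values (I = 83 cd/m², τ = 0.7, S_retina = 18 mm²,
  a_c = 1 µm², S_pupil = 0.1–3.2 mm²) the literal result is three orders
  of magnitude below the published 2.4–78.3 × 10⁶ R/cone/s range, which
  evidently folds in an unstated luminance-to-photon-flux conversion.
  The implementation documents rather than reproduces that constant; only
  ratios across pupil sizes (e.g. 32× from 0.1 to 3.2 mm²) are treated
  as meaningful.

## Known limitations

* The wrapped-Gaussian fit assumes unimodal direction tuning with peaks
  exactly 180° apart; strongly bimodal non-axial cells are mis-fitted.
* The receptive-field model is linear; ON/OFF rectification enters only
  through the separate indicator channels, not through output
  nonlinearities.
* The circular paired test's p-value is approximate (interval inversion),
  accurate near conventional levels but coarse in the far tails.
* Session serialization uses CSV/YAML directories — portable and
  diff-able, but not suited to very large raw-movie storage.
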