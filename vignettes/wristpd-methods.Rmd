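---
title: "Methods: digital motor-symptom indicators from wrist accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital motor-symptom indicators from wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinic-based rating of Parkinson's disease motor symptoms (MDS-UPDRS Part
III) is episodic and rater-dependent. A smartwatch worn on the more affected
wrist during a short, standardized exercise protocol yields triaxial
acceleration streams whose time- and frequency-domain summaries track the
clinical ratings of tremor and bradykinesia. `wristpd` implements the
offline analysis for such recordings: session ingestion, gravity removal,
per-segment and sliding-window feature extraction, continuous resting-tremor
interval labeling, and the statistical surface (Pearson correlation against
item scores; t-SNE embeddings brushed by severity). Because raw clinical
recordings are not required for development or testing, a synthetic-cohort
simulator generates protocol-structured signals with known ground truth.

## The protocol and label taxonomy

Each weekly *single trial* records eight exercises interleaved with rest
intervals and postural transitions, at 50 Hz. Per-sample labels use: 0 =
postural transition, 1 = resting interval, 2–8 = exercises 2–8. Exercise 1
(the 30 s rest-tremor posture) shares label 1 with the inter-exercise rest
intervals; the two are behaviorally the same state (relaxed, supported limb),
and downstream analyses that need "the exercise" take the longest label-1
segment of a trial. Six exercises carry MDS-UPDRS item scores 0–4:
rest-tremor posture (3.17), postural tremor (3.15), finger tapping (3.4),
hand open/close (3.5), pronation-supination (3.6), gait (3.10). The
hand-to-chest exercise (3) has no standardized score and sit-to-stand (7)
yields only ~2 s of signal per trial, so both are excluded from the
correlation analysis.

## The simulator

`simulate_trial()` builds `gravity + voluntary movement + tremor + white
noise`, all in m/s² (Android sensor convention: gravity included, magnitude
9.81).

* **Tremor** is an amplitude-modulated sinusoid whose instantaneous
  frequency performs a bounded random walk (±0.25 Hz) around a per-subject
  fundamental drawn uniformly from 3.5–7.5 Hz, so the spectrum is a narrow
  band, not a line. Amplitude is `0.25 · score` m/s² (zero at score 0, 1.0
  m/s² at score 4). It is injected during rest intervals (scored by item
  3.17) and the postural hold (item 3.15).
* **Pronation-supination** cycles at `2.0 − 0.3 · score` Hz with amplitude
  `1.5 − 0.25 · score` m/s²: severity slows and attenuates the movement, and
  the impaired fundamental falls inside the 1–4 Hz dyskinesia band.
* **Direction of oscillation.** Wrist tremor and wrist exercises tilt the
  sensor, so their dominant accelerometer signature is the oscillating
  projection of gravity. Simulated oscillations therefore use a direction
  with a strong gravity-aligned component plus a random transverse part.
  This is not cosmetic — it is what allows any norm-based analysis to see
  the oscillation at its true frequency (next section).
* **Other exercises** (hand-to-chest, tapping, hand open/close,
  sit-to-stand, gait) are simple parametric oscillation/burst templates.
  They exist so every label is populated with plausible energy; only the
  rest-tremor and pronation-supination channels are quantitatively
  meaningful.
* Transitions are 1–3 s low-frequency ramps; rest intervals default to
  20 s; unspecified durations (hand-to-chest 15 s, sit-to-stand 2 s, gait
  20 s) and the sensor noise floor (0.05 m/s² per axis, a typical consumer
  IMU value) are package choices, stated once and not tuned.

Determinism: every trial's RNG stream is derived from the master seed plus
subject id and week, so the same configuration reproduces byte-identical
files.

## Gravity removal and the two norm routes

Per-axis gravity removal uses a third-order Butterworth high-pass at 0.5 Hz.
The filter is applied in direct form II transposed with steady-state initial
conditions scaled by the first sample, plus odd-reflection padding; in
zero-phase mode it runs forward and backward (squared magnitude, no phase
distortion). A constant input maps to an exactly-zero output, and startup
transients are suppressed even on few-second segments. A causal single-pass
mode is retained for streaming-equivalent analyses.

There are two defensible orders for combining filtering with the Euclidean
norm, and they measure different things:

* `movement_norm()` — high-pass each axis, then take the norm. This removes
  gravity exactly, but the norm of a zero-mean oscillation is a *rectified*
  signal: a tremor at f₀ re-appears at 2f₀ and in the envelope, not at f₀.
* `norm_highpass()` — take the norm of the raw axes, then high-pass.
  Because movement accelerations at the wrist are small relative to gravity,
  `|g + m(t)| ≈ |g| + m(t)·ĝ`: the gravity offset is a sign-preserving
  carrier, and an oscillation keeps its power at f₀.

Symptom-band analysis (tremor band 3.5–7.5 Hz, dyskinesia band 1–4 Hz) is
only physically meaningful on the sign-preserved route, so the per-segment
feature pipeline and the tremor labeler use `norm_highpass()` by default
(`segment_feature_table(..., norm_fun = movement_norm)` selects the other
route). On a 40-trial synthetic cohort the choice is decisive: the
tremor-band/severity correlation is r ≈ 0.9 on the sign-preserved route
versus r ≈ 0.4 rectified, and the pronation-supination 1–4 Hz correlation
collapses from r ≈ −1 to r ≈ −0.5 when rectification folds the slowed
fundamental back into the band. The windowed feature set is unaffected by
this choice for its axis channels (they are signed either way); only its
norm channel is rectified, which is conventional for activity-recognition
features.

## Features

**Per-segment (15 features).** On the whole segment of the high-passed norm:
standard deviation, mean, median, 25th/75th percentiles (type-7 linear
interpolation between order statistics), bias-corrected (adjusted
Fisher–Pearson) skewness, maximum, minimum; plus band powers for freezing of
gait (3–8 Hz), tremor (4–6), extended tremor (3–8), bradykinesia/dyskinesia
(0–3), gait (1–3), dyskinesia (1–4) and the full movement band (0–20 Hz).
Segments shorter than 2 s report time features only (band powers missing);
constant segments report skewness as missing rather than a silent NaN.

**Spectral estimator.** Band power is the trapezoidal integral of a Welch
power spectral density (Hann window, mean-detrended segments of length
`min(256, L)`, 50 % overlap, one-sided density scaling) with the density
linearly interpolated at the band edges, which makes disjoint bands sharing
an edge add exactly to their union. The estimator is validated in the test
suite against an independent single-window periodogram oracle; Parseval
(full-band power = variance) holds within 2 % and a unit 5 Hz sine yields
A²/2 in the 4–6 Hz band within 5 %.

**Sliding-window set.** Activity-recognition features on 2.56 s / 128-sample
windows with 50 % overlap, computed per channel over the three filtered
axes, their norm, and the jerk (scaled first difference) of all four:
location/spread/shape statistics, energy, lag-1 autocorrelation, zero
crossings, histogram entropy, dominant frequency, spectral centroid,
normalized spectral entropy, the seven band energies, and signal-magnitude
area per triaxial group (186 columns). Windows straddling a segment boundary
are dropped, not truncated, so each row is purely one exercise; each row
carries its exercise label and the trial's item score (healthy controls
score 0 on every item). This registry reproduces the standard feature
*families* rather than any fixed published list of 290 columns; it feeds
exploratory embedding, not the correlation analysis.

## Resting-tremor interval labeling

Rest-segment tremor is labeled from the windowed 3.5–7.5 Hz band power of
the high-passed norm against a threshold. Window decisions are converted to
sample labels by a strict-majority vote over the windows covering each
sample (plain union would dilate every burst by nearly a full window at each
end); gaps ≤ 0.5 s are merged and spans < 1 s dropped, yielding intervals a
reviewer could edit. Raising the threshold can only shrink the labeled
duration.

Because published empirical thresholds for such detectors are rarely
transferable, `calibrate_threshold()` provides a reproducible surrogate: it
pools ground-truthed rest windows across a simulated cohort and sweeps all
midpoints between observed band powers for the maximum Youden J. On
simulated cohorts with the default amplitude map the calibrated threshold
reaches window-level sensitivity and specificity of 1.0; on real data,
where tremor is intermittent and amplitudes graded, both would be lower.

## Statistical surface

`pearson_cor()` implements the product-moment formula directly with the
two-sided p-value from the t distribution on n−2 degrees of freedom
(cross-checked in tests against `cor.test` and a brute-force oracle to
1e-12); zero-variance input is an explicit error, not a silent NaN.
`correlation_matrix()` pairs each scored exercise with its item, drops
missing trials pairwise per cell, reports unadjusted p-values by default
(a Benjamini–Hochberg option exists), and marks undefined cells as missing.

`tsne_embed()` standardizes feature columns, drops constant or non-finite
ones, and runs Barnes–Hut t-SNE with PCA initialization, perplexity 30,
learning rate `max(50, n/12)` and 1000 iterations under a fixed seed —
chosen for reproducibility; t-SNE geometry is otherwise not identifiable
across implementations. The input table is never modified.

## Problem sizes and what the tests show

The test suite and the acceptance script run on synthetic cohorts of 2–40
trials (10 subjects × 4 weeks for parameter recovery; 6 subjects, half
controls, for threshold calibration; 200 points in 10 dimensions for the
embedding check) — sizes chosen so the whole suite completes in about a
minute while every estimate remains well inside its asymptotic regime.
Passing tests demonstrate that the pipeline recovers the structure *the
simulator injects*: linear severity-amplitude maps, stationary band-limited
tremor, noiseless label boundaries and complete scores. Real recordings add
intermittent tremor, voluntary-movement artifacts inside rest intervals,
device orientation changes, transmission gaps (reported, never interpolated
— infill would bias band powers) and rater disagreement; correlations of
the size seen here (|r| > 0.95) are an upper bound set by the simulator's
determinism, not a clinical claim. The package's correlations on real data
should be expected in the moderate-to-strong range reported in the wearable
Parkinson's literature, not near unity.

## Known limitations

* The voluntary-movement templates are not biomechanical; gait, tapping and
  sit-to-stand channels are placeholders with plausible spectra.
* No gyroscope/magnetometer channels and no medication ON/OFF dynamics are
  modeled.
* The gravity-carrier linearization behind `norm_highpass()` degrades when
  movement accelerations approach 1 g (vigorous gait); for such segments the
  axis-filtered route is the safer spectral reference.
* Tremor labeling assumes the rest segments were identified upstream; it
  does not separate rest from action tremor within a segment.
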