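---
title: "Decoding pain intensity from pre- and post-stimulus brain activity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding pain intensity from pre- and post-stimulus brain activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Perceived pain intensity varies strongly from trial to trial even when the
nociceptive stimulus is physically identical. Part of that variability is
carried by the *post-stimulus* brain response (the evoked low-frequency
response and induced alpha/gamma power changes in EEG; the hemodynamic
response peak in fMRI), and part by the *pre-stimulus* brain state present
just before the stimulus arrives. `paindecode` implements a three-stage
pipeline that (1) turns epoched single-electrode EEG or 4-D BOLD series into
trial-by-feature matrices with pre/post phase tags, (2) discovers
group-level pain-related patterns, and (3) predicts single-trial pain with
cross-validated linear support-vector models, comparing decoders built on
post-stimulus features alone ("Post") against decoders that add
pre-stimulus features ("Pre+Post").

Because no public single-trial cohort accompanies this design, the package
ships a synthetic-cohort generator (`generate_cohort()`) with planted ground
truth, so every stage can be validated quantitatively.

## Stage 1 — features

**EEG.** Each trial is an epoch from −500 to 1000 ms around stimulus onset
at 1000 Hz (electrode-level data; one electrode per analysis).
`compute_spectrogram()` applies a short-time Fourier transform with a fixed
200 ms Hann window, 10 ms hop, and zero-padding to the next power of two at
or above the sampling rate (about 1 Hz frequency spacing at 1000 Hz). Each
windowed segment is demeaned before the DFT so DC offsets cannot leak into
low-frequency bins. Only fully contained windows are emitted: a "pre" pixel
never mixes post-onset samples, which would otherwise leak evoked activity
into the pre-stimulus state. Analysis windows are half-open, `[-500, 0)` and
`[0, 1000)` ms; a bin centered exactly at 0 ms counts as post-stimulus.
Power is raw squared magnitude by default (`tf_log = TRUE` switches to
log10; the default keeps features in familiar µV² units).

**fMRI.** For each trial, the *onset scan* is the last scan whose
acquisition start is at or before stimulus onset (pre-stimulus state) and
the *peak scan* is the 4th scan after it (TR 1.5 s, so about 6 s, the
empirical peak of the hemodynamic response). In-mask voxels are flattened in
column-major array order, which is stable across serialization. Scan indices
are reported 0-based to match acquisition numbering: onset at 15.0 s with TR
1.5 s gives scans 10 and 14.

**Energy normalization.** Stimuli are delivered at four energies with very
different mean ratings, so features and ratings are normalized by removing
energy-group means (`normalize_by_energy()`). This isolates the
trial-to-trial fluctuation under identical stimulation — the only component
a pre-stimulus state can, by causality, predict (stimulus energies are
randomized). Group means are retained so predictions can be mapped back to
the 0–10 VAS scale, and so the classifier can operate on raw-scale features
(below).

## Stage 2 — pattern discovery

Per subject, a linear model links the normalized rating to all pre- and
post-stimulus features. With tens of thousands of collinear features and
about 40 trials, the model is fit by partial least squares regression using
the NIPALS algorithm (`fit_plsr_nipals()`, default 3 components). Features
are centered and, by default, unit-scaled internally; coefficients are
back-transformed to raw units. The scaling default is a deliberate design
choice: spectrogram power follows an approximately 1/f spectrum and spans
about four orders of magnitude between 1 and 100 Hz, and without scaling
the PLSR components are monopolized by high-variance low-frequency
features, so genuine gamma-band effects receive unstable coefficients. With
as many components as the rank of X the (unscaled) fit equals ordinary
least squares; the test suite verifies this against a normal-equations
oracle and cross-checks predictions against an independent PLS
implementation.

Subjects whose ratings do not vary (no variable sensation) are excluded
with a logged reason, mirroring standard practice for this paradigm.

Group inference (`cluster_permutation_test()`): each feature's coefficient
is tested against zero across subjects with a one-sample t-test; features
with two-tailed p below 0.05 are clustered by grid connectivity
(8-neighbour on the time-frequency grid, 6-neighbour on the voxel grid),
separately for positive and negative effects and separately per phase, so a
pre-stimulus cluster never merges across the onset boundary with a
post-stimulus one. Each cluster's mass (sum of |t|) is compared with a
pooled null distribution of the maximum cluster mass obtained by randomly
flipping the sign of whole subject maps — the flip unit is the subject map,
which preserves within-map spatial correlation while imposing the symmetric
null. Cluster p-values use the standard `(1 + #exceedances) / (n_perm + 1)`
estimator, so they are bounded below by `1/(n_perm + 1)` and the procedure
controls the family-wise error rate by construction; a 200-dataset
simulation in the acceptance suite verifies the realized FWER sits inside
the exact binomial band around 0.05. Zero-variance features are assigned
t = 0 and excluded from clustering. Cluster labelling is deterministic
(scan order by grid coordinate).

`extract_patterns()` turns each significant cluster into a named pattern
with a modulation sign (the sign of its mean t); on the time-frequency grid
names are auto-generated from phase and frequency band.

## Stage 3 — decoding

Per subject, each pattern contributes one predictor: the mean feature value
over its coordinates (aggregation `"mean"`, the default; `"pixels"` keeps
every coordinate for sensitivity analyses). Two decoders run under
leave-one-out cross-validation with a linear kernel, C = 1, and no inner
tuning loop:

* `loocv_classify()` — support-vector classification of low pain (VAS < 5)
  versus high pain (VAS ≥ 5; a rating of exactly 5 is high). Classification
  consumes features on the **raw** scale (energy-group means added back):
  stimulus-driven response amplitude is genuinely informative about high
  versus low pain, and a classifier restricted to energy-normalized features
  could never see stimulus energy, capping its accuracy near the majority
  rate. This reading also reproduces the characteristic split in which
  post-stimulus patterns decode far better (~70%+) than pre-stimulus
  patterns (~55–60%), whose features are independent of energy by design.
* `loocv_regress()` — epsilon-SVR (epsilon = 0.1) of the continuous rating.
  Training targets are the ratings minus **training-fold** energy-group
  means; with `target_mode = "raw"` the training-fold mean of the held-out
  trial's energy is added back and the MAE is measured on the 0–10 scale,
  with `"normalized"` everything stays on the fluctuation scale (used for
  pre-stimulus patterns, which cannot forecast stimulus energy).

Within every fold, predictors are z-scored with training-fold statistics
and energy means are recomputed from the training fold, so nothing about
the held-out trial's rating can influence its own prediction; a dedicated
test corrupts the held-out rating and asserts the prediction is unchanged.
The one quantity shared across folds is the global per-energy feature
centering performed at extraction time, which mirrors the original
procedure and involves only features, never the held-out rating.

Aggregate metrics are the confusion-table sensitivity and specificity with
high pain as the positive class, accuracy, and the mean absolute error
`MAE = (1/P) Σ |R_p − R̂_p|`. All aggregates are recomputable from the
stored per-trial records.

`compare_feature_sets()` runs a paired two-tailed t-test on per-subject
metrics (Pre+Post versus Post). Degenerate inputs are flagged instead of
silently tested: identical values give p = 1 with flag `"identical"`; a
constant nonzero difference has no t statistic and is flagged
`"constant-difference"` with the mean difference reported.

`rank_patterns()` evaluates each pattern alone; pre-phase patterns are
scored on the normalized target, post-phase patterns on the raw target.
Accuracy is tested against 0.5 across subjects; note that when the high/low
classes are imbalanced (as here, where mean ratings sit above 5), the
operative chance level is the majority-class rate rather than 0.5, and the
simulation suite uses the per-subject majority rate when checking that
unexpressed patterns stay at chance. An optional permuted-rating baseline
(`n_mae_null`) provides the analogous chance reference for the MAE.

`selection_mode` exposes two analysis designs: `"paper-faithful"` (default)
identifies patterns once on the full cohort before per-subject LOOCV —
reproducing the mild selection circularity of the original design — while
`"loso"` re-identifies patterns with the predicted subject excluded.

## The synthetic cohort generator

`generate_cohort()` emulates the study design: per subject, 4 stimulus
energies × 10 trials in pseudorandom order; per-trial ratings

    rating = clip(energy_mean + s_pre + s_post + noise, 0, 10)

with energy means (3.81, 4.86, 6.63, 7.75), `s_pre = 0.6 · z_pre`,
`s_post = 0.8 · z_post` (standard-normal latents), and noise SD 1.0. The
rating-noise SD matches the reported within-energy rating SDs (≈1.0–1.4);
the two state SDs were chosen once so that the total within-energy SD
(≈1.41) stays in that range, with the post-stimulus response contributing
somewhat more than the pre-stimulus state. The pre-stimulus latent is drawn
i.i.d. across trials by default (an AR(1) option, `ar1_phi`, exists for
robustness checks) and is independent of stimulus energy by construction.
Clipping to [0, 10] affects well under 5% of trials at these settings; the
generator warns otherwise. The exact rating decomposition is stored in the
ground truth and tests assert it sums identically.

**Effect sizes.** A planted pattern's `d` is the *standardized region-mean
slope*: the pattern's region-mean feature moves `d` trial-to-trial
(background) standard deviations per standard deviation of its latent state,
so `cor(region mean, latent) = d / sqrt(1 + d²)`. This region-level
definition was chosen because the decoder consumes region means, making
decoding difficulty directly controlled by `d`. A calibration test recovers
the realized `d` from the ground-truth latents to within 20% at the default
settings.

**EEG expression.** The background is spectrally synthesized 1/f^1.3 noise
with an alpha bump and a white floor, with per-subject log-normal amplitude
scaling. Planted patterns are expressed as multi-tone bursts: tone
frequencies sit inside the declared band with a margin and 6 Hz spacing (so
tone mainlobes of the 200 ms analysis window barely overlap and the planted
power pattern is stable across the per-subject random tone phases); tone
amplitudes follow the background amplitude profile so the planted
signal-to-background ratio is uniform across the band; the envelope spans
the declared time range with generous cosine ramps (a full Hann envelope
for short ranges), keeping envelope sidelobes near −31 dB. The per-trial
burst amplitude is obtained by solving a quadratic that accounts exactly
for interference between the burst and that trial's background in the
complex STFT, so the realized region-mean power equals
`background + slope · (3 + sign · z)` by construction (the offset keeps
added power non-negative for |z| < 3). Post-stimulus patterns additionally
scale with stimulus energy, which the per-energy normalization removes
again — it matters only for raw-scale classification, as in real data.

**What the generator does not emulate.** Time-frequency uncertainty is
physical: a burst confined to a 7 Hz × 190 ms rectangle cannot avoid
spectral leakage of order the analysis window's mainlobe (±4–6 Hz), and
when the adjacent bands are much quieter than the planted band that leakage
is itself genuinely rating-correlated and hence detectable. Recovered
clusters for narrow alpha-band rectangles are therefore systematically
wider than their declared masks, and very large planted rectangles are
recovered partially (region-level `d` dilutes per-pixel signal-to-noise in
proportion to region size). Passing recovery tests on the mid-sized
patterns shows the inference machinery is sound; the mismatch on the
extreme geometries reflects the resolution of the 200 ms-window analysis,
not an implementation property. The generator also makes no claim of
biophysical realism (no head model, no HRF dynamics, no artifacts), so
passing tests demonstrate statistical correctness of the pipeline, not
performance on real recordings.

**fMRI mode** uses a small grid (20 × 20 × 16 voxels, ellipsoidal brain
mask, TR 1.5 s, inter-stimulus intervals uniform in 10–15 s) so the whole
pipeline runs in minutes. The background is spatially smoothed white noise
(separable Gaussian, SD 1.2 voxels); planted spherical blobs (radius 2–2.5
voxels) receive uniform offsets on the onset or peak scans with the same
slope calibration as EEG — exact there, because the signal adds directly in
feature space.

## Numerical choices and degenerate inputs

* STFT: only fully contained windows; per-segment demeaning; `nfft` at
  least the window length; frequency range must respect Nyquist.
* NIPALS: rank exhaustion reduces the component count with a warning;
  constant ratings and non-finite values are errors; the rank tolerance is
  referenced to the feature scale so unit choices do not change behavior.
* Permutation test: below 100 permutations a warning is issued (p-value
  resolution); the permutation RNG is seeded explicitly and results are
  bit-reproducible.
* SVR folds whose training targets all fit inside the epsilon tube (no
  support vectors) predict the training-target mean.
* Classification requires at least two trials per class; subjects failing
  this are skipped with a logged reason rather than aborting the cohort.
* All cohort and feature files use IEEE-754 little-endian doubles with JSON
  or CSV sidecars written at full precision, so round trips are exact.

## Problem sizes used in the automated checks

The test suite exercises the pipeline at sizes a laptop handles in minutes:
cohorts of 5–30 subjects with the standard 40 trials each; the FWER
calibration uses 200 null datasets of 20 subjects on a 30 × 50 grid with
500 permutations; recovery uses 25 subjects at d = 1 with 1000
permutations; ranking uses 50 replicate 10-subject cohorts. These sizes
were chosen to give the relevant binomial/t confidence bands reasonable
width, and the acceptance script reports the cohort size next to every
quantity it writes.

## Known limitations

* Single-electrode EEG only; multi-channel fusion is out of scope.
* No preprocessing (filtering, artifact rejection, ICA, registration,
  HRF modelling): inputs are assumed epoched/registered upstream.
* Cross-subject transfer decoding is not implemented; all decoding is
  within-subject.
* The exact permutation scheme of the original analysis is documented only
  in its cited methodological reference; the choices here (mass statistic,
  pooled max-null, 8/6-neighbour connectivity, point alpha 0.05) are
  common defaults and are all configurable.
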