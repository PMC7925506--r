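---
title: "Methods: single-sensor smartphone gait analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-sensor smartphone gait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitwave)
```

## The problem

A single smartphone strapped to the calf records tri-axial acceleration
(m/s^2) and angular rate (rad/s) while a person walks a straight path for 10
or 20 seconds. The goal is to decide, from that one trial, whether the gait
is physiological or pathological (post-stroke hemiplegic). One sensor cannot
resolve the full gait-cycle phase anatomy, so the pipeline targets five
summary features that are robustly recoverable from a calf-mounted IMU:

| feature | unit | meaning |
|---|---|---|
| mean cycle duration | s | mean stride (same-foot contact to contact) time |
| cycle regularity | s | standard deviation of stride times; near 0 = regular |
| cadence | cycles/min | projected strides per minute |
| PSD peak, acceleration | dB | maximum of the acceleration periodogram |
| PSD peak, gyroscope | dB | maximum of the angular-rate periodogram |

## Signal model and preprocessing

Each magnitude signal is modeled as `s(n) = f(n) + sigma * e(n)` with `e`
zero-mean unit-variance Gaussian white noise. The chain is:

1. **Magnitude.** The per-sample Euclidean norm of the three channels.
   Gravity is retained: the acceleration magnitude is offset-positive, and
   the DC component is irrelevant downstream because the periodogram removes
   the mean and the valley search is amplitude-relative.
2. **Resampling to 200 Hz.** Handsets deliver anything from 50 to 350 Hz.
   A rational-factor polyphase resampler (Kaiser-windowed sinc, 20·max(p,q)+1
   taps, cutoff at the smaller Nyquist frequency) brings every trial to a
   common 200 Hz. The gait-relevant band (below ~25 Hz) passes with ripple
   under 0.1%; tests assert RMS reconstruction error below 1% of amplitude
   for band-limited tones from every pool rate.
3. **Wavelet denoising.** Symlet-4 decomposition at `W = 4` levels
   (requiring at least 128 samples), soft thresholding of each detail level
   at `t_w = sigma_w * sqrt(2 ln L)` with `sigma_w` the per-level median
   absolute deviation of the detail coefficients divided by 0.6745, and
   reconstruction from the untouched level-4 approximation. `L` is the full
   signal length. The symlet order (4) is a package choice — the "least
   asymmetric" family does not pin down an order — and near-linear phase is
   what preserves valley timing.
4. **Mallat filter bank.** Four low-pass/decimate-by-two stages take the
   denoised 200 Hz signal to 12.5 Hz, comfortably above twice the ~1.8 Hz
   step frequency of healthy walking. Each stage keeps `ceil(n/2)`
   coefficients aligned with the even input samples, so durations halve
   exactly and the accumulated group delay stays below one output sample;
   outputs are divided by `sqrt(2)` per stage so constants map to
   themselves.

The DWT uses half-point symmetric extension at both ends; decomposition and
reconstruction were verified coefficient-for-coefficient against an
independent reference implementation and satisfy perfect reconstruction to
1e-9 on random signals of odd and even length.

## Spectral features and the valley search

PSDs are plain (rectangular-window) periodograms of the mean-removed
**denoised, unfiltered 200 Hz** signals, reported as `10 log10(PSD)` with
exact one-sided Parseval scaling; the peak excludes the DC bin. Walking
places the gyroscope fundamental at the stride frequency `1/T` and the
acceleration peak at the step frequency `2/T` (each foot contact excites the
magnitude), so the expected step interval is estimated twice —
`1/f_accel` and `1/(2 f_gyro)` — and averaged.

Strides are segmented on the 12.5 Hz acceleration magnitude: the first
valley is the global minimum over the first 1.5 step windows, and each next
valley is the signal minimum within ±30% of one stride (two step windows)
around the previous valley plus one stride. The doubling of the per-step
window into a per-stride hop is deliberate: with one instrumented leg, only
that leg's contacts produce deep minima, and contralateral contacts are
attenuated. Both the ±30% search fraction and the 1.5-window first-valley
span are package choices exposed as arguments; the search can optionally run
on the 200 Hz denoised signal (`valley_stage = "denoised"`). From the valley
array `V`, stride durations are `C_d[k] = V[k+1] - V[k]`, regularity is
their sample standard deviation (`n - 1` denominator, a package choice), and
cadence is `60 (|V|-1) / (V_last - V_first)`, which is algebraically
`60 / mean(C_d)`.

Features are min-max normalized per column to `[0, 1]`
(`a_j` = maximum, `b_j` = minimum over patterns). Normalization is fitted on
the full dataset before cross-validation, mirroring the stated order of
operations of the study protocol; this leaks the test extrema into training
scaling, which is mild but real — `apply_normalization()` supports
fit-on-train-only workflows if wanted.

## The synthetic cohort

The clinical recordings behind the original study are not public, so the
package ships a generator that emulates their documented statistical shape
and serves as ground truth for every downstream stage:

- 35 healthy + 25 pathological trials; 41 of 10 s and 19 of 20 s, 12 of the
  20 s trials pathological; native rates drawn from
  {50, 100, 128, 200, 256, 350} Hz.
- The clean acceleration magnitude is gravity plus a train of biphasic
  contact transients (negative first derivative of a Gaussian, width
  `T/10`: a spike followed by a valley) at alternating left/right contacts
  spaced `T/2`, the contralateral side scaled by the asymmetry ratio. The
  clean gyroscope magnitude oscillates at the stride fundamental, which
  forces the acceleration peak onto the gyroscope's second harmonic by
  construction.
- Class defaults: healthy stride 1.1 s (≈1.8 Hz steps), jitter 0.02 s,
  asymmetry ratio 0.9, gyro amplitude 1.5 rad/s; pathological stride 1.8 s,
  jitter 0.15 s, ratio 0.4, gyro amplitude 0.9 rad/s. The pathological
  waveform parameters are package choices (slower, more irregular, more
  asymmetric, weaker rotation — the qualitative hemiplegic signature);
  within-cohort spread is log-normal with 12–25% CV so the classes overlap
  rather than separate trivially. Noise sigma defaults to 0.25 per
  magnitude.
- `separation = 2` moves the class parameter means apart geometrically
  about their midpoint (clipping the asymmetry ratio to `[0, 1]` and
  jitter to `T/6`) — the well-separated regime used by the classifier
  sanity checks.

What the generator does **not** model: limb kinematics (channels are a fixed
unit-vector split of the magnitude), sensor bias/drift, magnetometer data,
and real hemiplegic waveform morphology. Passing tests therefore demonstrate
that the pipeline recovers the structure this model encodes — timing,
regularity, spectral amplitude — not clinical performance on real patients.

## Classifiers and the benchmark

Nine classifiers run over **all 31 non-empty subsets** of the five features
under repeated stratified cross-validation: disjoint test folds of 10
patterns (6 folds on 60 trials, per-fold class counts within one of the
global ratio), accuracy pooled over folds, 10 repeats with fresh seeded
partitions; reported values are mean ± standard deviation over repeats.
Winners are chosen by mean accuracy, ties broken toward fewer features, then
lexicographic mask order.

Stated hyperparameters: KNN `K = 5` Euclidean (all neighbours tied at the
K-th distance vote; vote ties go to the first class level); naive Bayes with
per-feature Gaussian-kernel densities (Silverman's bandwidth, a package
choice); SVM with RBF kernel, `C = 1`, kernel scale `1/(N·mean feature
variance)`; CART with Gini splits, frequency priors, grown unpruned; PNN
with spread 0.1 in the normalized space; FIS from subtractive clustering
(influence 0.5, squash 1.5·0.5, accept/reject 0.5/0.15) with one
first-order Sugeno rule per center, Gaussian memberships of width
`0.5·range/sqrt(8)`, consequents by least squares with a 1e-8 ridge
fallback; neuro-fuzzy with one Gaussian cluster per class initialized at
class means/SDs, trained by scaled conjugate gradient on cross-entropy for
at most 100 epochs (only improving steps are accepted, so the loss trace is
non-increasing). LDA/QDA are Gaussian discriminants with a 1e-6 diagonal
ridge so near-constant features in a training split cannot make the
covariance singular.

The original study's "10-fold" wording describes 6 iterations of 10 test
patterns on 60 records; the package implements that literal protocol with
`test_size` configurable.

## Numerical choices and limitations

- Degenerate inputs fail loudly and early: fewer than 128 samples at the
  denoiser, constant signals at the periodogram ("no spectral peak"), fewer
  than two valleys at segmentation ("insufficient strides"); a constant
  feature column normalizes to 0 with a warning instead of failing.
- All randomness is seed-driven at the API (`generate_*`, fold partitions);
  classifiers themselves are deterministic given the data.
- Problem sizes in the tests — 60-trial cohorts, 20 recovery seeds, 10 CV
  repeats — match the study protocol's scale while keeping the whole suite
  near two minutes on a laptop-class core.
- Known limitations: the second-harmonic relation between the two spectral
  peaks can fail on real, noisy recordings (no corrective action is taken
  when it does); the valley search assumes quasi-periodic gait and will
  produce poor strides for stop-and-go walking; accuracy figures obtained
  on synthetic cohorts characterize the pipeline, not clinical
  discriminability.
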