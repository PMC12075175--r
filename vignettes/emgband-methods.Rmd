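---
title: "Decoding gestures from medium-density surface EMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding gestures from medium-density surface EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgband)
```

## The problem

Myoelectric control decodes hand gestures from surface electromyography
(EMG), the electrical activity of contracting forearm muscles measured on
the skin. Conventional armbands carry few electrodes (low density, ~7
channels) and limited spatial resolution; high-density grids (64+)
resolve spatial detail but are impractical to wear. `emgband` implements
the full decoding stack for a *medium-density* configuration -- a ring of 7
sensor nodes with 3 channels each, 21 channels at 1,067 Hz -- together with
a synthetic session generator, so every stage can be exercised and tested
against ground truth without hardware.

The pipeline is: simulate (or load) a labeled session, condition the
signal, extract per-window descriptor features, decode gestures with one
of three classifiers, explain the trained networks with gradient saliency,
and compare montages and decoders with nonparametric statistics.

## The synthetic session generator

`generate_session()` emulates a cued recording protocol: six gesture
classes (power, lateral pinch, tripod, pointer, open, rest), 10
repetitions each, 6 s of movement followed by 6 s of relaxation per trial,
with per-sample labels -- 60 trials in the default session. Trial order is
block-randomized from the protocol seed: each block contains every gesture
once in a random order, which guarantees balanced, interleaved classes and
makes stratified trial-wise splits straightforward.

Each channel is synthesized as

    signal = carrier x (amplitude x envelope) + baseline noise

* **Carrier**: white Gaussian noise band-limited to 30--350 Hz, the
  phenomenological standard for surface EMG (zero-mean, broadband,
  amplitude-modulated by contraction intensity). The synthesis filter is a
  6th-order Butterworth (steeper than the order-2 analysis chain, so more
  than 95% of carrier power lies strictly inside the band); one second of
  warm-up is synthesized and discarded so no session carries the filter
  startup transient. Channels within one node
  share a common carrier component (correlation 0.6 by default),
  reflecting how closely spaced electrodes over the same musculature see
  similar but not identical signals.
* **Envelope**: a gate over the scheduled movement interval with 100 ms
  raised-cosine onset/offset ramps (muscle force does not step
  instantaneously; the ramp also avoids filter transients). A square
  envelope (`ramp_s = 0`) is available for detector benchmarks.
* **Amplitude**: set per channel so that a channel with activation gain 1
  realises the configured signal-to-noise target in the on/off
  variance-ratio sense used throughout the package,
  `SNR = 10*log10(var_ON/var_OFF - 1)`. The default target is 9.54 dB,
  i.e. an ON/OFF variance ratio of 10, a realistic figure for good surface
  recordings.
* **Spatial model**: a gesture-by-channel activation gain matrix is the
  ground truth that decoders and saliency maps are judged against. The
  default pattern assigns each gesture a node-level profile crossed with a
  within-node profile, and deliberately makes two gesture pairs
  (power/lateral pinch, tripod/pointer) identical on the middle channel of
  every node while differing on the side channels. This encodes the
  physiological premise of the medium-density design -- adjacent electrode
  sites carry genuinely complementary information -- and gives the
  low-density montage a real information deficit rather than a merely
  statistical one.

What the generator does **not** emulate: motor-unit recruitment and firing
statistics, electrode-skin impedance, electrode shift, fatigue,
limb-position effects, or power-line interference. Tests passing on this
synthetic family therefore demonstrate algorithmic correctness and the
stated structural claims, not clinical performance on real recordings.

## Signal conditioning

`apply_filter_chain()` reproduces the acquisition front end in software: a
second-order IIR Butterworth band-pass (30--350 Hz) followed by a 50/60 Hz
notch. The notch is an RBJ biquad with quality factor Q = 30 (about 1.7 Hz
wide at 50 Hz); Q is exposed because no bandwidth is canonical. Offline
the chain runs forward-backward (zero phase, squared magnitude response);
a causal single-pass mode mirrors a streaming front end. Filtering is
strictly per channel.

Windowing uses the overlapping scheme with 281.1 ms windows and a 9.3 ms
step. Sample counts are `round(ms * fs / 1000)`, giving 300-sample windows
with a 10-sample step at 1,067 Hz; the window count over `n` samples is
`floor((n - L)/S) + 1`.

## Activity detection and SNR

`detect_on_off()` implements double-threshold detection. The signal is
rectified about its baseline mean and smoothed with a centred moving
average of `m` samples. Baseline statistics come from the quietest
`baseline_s`-second stretch and are refined once from the pooled OFF
states of a first pass -- the quietest-stretch estimate is biased low by
its minimum-variance selection, and the pooled re-estimate removes that
bias. Two thresholds follow: `LT = mu_n + k1*sigma_n` (candidate
activity) and `UT = mu_n + k2*sigma_n` (confirmation), defaults
k1 = 3, k2 = 5, m = 30 (~28 ms), all exposed.

Implementation choices that matter:

* A candidate run above LT becomes ON only if it lasts at least `m`
  samples **and** stays above UT for at least `m` consecutive samples.
  The rectified-noise envelope is right-skewed, so a single-sample
  excursion above UT is not evidence of contraction; requiring sustained
  supra-UT activity is what makes the false-alarm rate negligible without
  touching the thresholds.
* Variations of the detector output shorter than `m` are rejected in both
  directions: sub-`m` OFF gaps inside a contraction are merged first, then
  stray short ON runs are dropped.
* Per-state variances (of the raw signal -- rectification is used only for
  detection) are computed on state interiors, with an `m`-sample guard
  band at each boundary, so transition samples do not contaminate the OFF
  statistics. The smoother's half-window edges are outside the analyzed
  span.

`compute_snr()` averages per-state variances and reports
`10*log10(sigma_s^2/sigma_n^2 - 1)` plus the baseline noise level `e_n`
(mean OFF standard deviation). A non-positive ratio argument is flagged
(`-Inf` dB), never thrown.

## Descriptor features

Six per-window, per-channel time-domain descriptors form the decoder
input, in fixed order: the integral square descriptor (power); its
difference with the normalized root-square coefficient of the first and of
the second difference; the mean logarithm kernel (a geometric-mean
magnitude); the mean square root; and the mean second difference. Three
conventions were genuinely open and are fixed as follows: the
normalization constant of the difference terms defaults to the window
length `n`; logarithm and square root act on magnitudes (raw EMG is
zero-mean, so signs are inevitable) with a 1e-8 stabilizer inside the log;
divisors stay `n` exactly as the formulas are printed. The sliding
implementation uses cumulative sums (every descriptor is a windowed sum of
a pointwise transform) and is tested to 1e-10 against literal summation.

Windows are tiled into non-overlapping model samples of `time_steps = 60`
consecutive windows -- the `[samples, time_steps, channels, features]`
tensor, `[N, 60, 21, 6]` at defaults. Tiling (rather than sliding) keeps
model samples disjoint. A sample's label is the majority raw-sample label
of its span; spans touching two different movement gestures are dropped.
Features are z-scored per channel-feature pair with statistics from the
training split only.

## Decoders

`fit_decoder()` is the single fitting surface; it returns an
`emg_decoder` with `print`, `summary` and `predict` methods.

**LDA** -- the classical baseline: a pooled-covariance linear discriminant
on flattened per-window vectors (channels x features), with shrinkage of
the covariance toward the scaled identity (lambda = 1e-3, automatically
raised if the pooled covariance is singular). A model sample is classified
by majority vote over its 60 windows, ties broken by mean posterior.

**Vanilla TCN** -- a stack of causal dilated 1-D convolutions along time
(kernel 3; dilations 1, 2, 4), each block followed by batch normalization,
ReLU and dropout, with global temporal average pooling and a softmax head.
Channel handling has two modes: `"flatten"` (default) folds channels into
the feature axis, the standard stacked-TCN practice; `"independent"`
shares the temporal weights across channels and pools channels before the
head, which makes the model provably blind to channel identity.

**STCN** -- the simultaneous spatio-temporal network: each block runs two
parallel branches on its input, the causal dilated temporal convolution
and a spatial convolution across the channel axis at each time step
(kernel 3, circular -- the electrodes form a closed ring around the
forearm, so channel 21 neighbours channel 1), merged by concatenation
(summation available), then batch normalization, ReLU and dropout.

Training is Adam (lr 1e-3, batch 32) on cross-entropy with early stopping
on a stratified validation split (patience 10, up to 100 epochs). These
training constants, the depth/width defaults (3 blocks, 32 filters) and
the merge rule are this package's choices; no canonical values exist for
this architecture family. All forward and backward passes are implemented
natively in base R; all randomness (initialisation, shuffling, dropout)
flows through the R RNG, so a fixed seed reproduces a fit bit-for-bit.
Tests and the bundled experiments use smaller instantiations (2 blocks, 6
to 8 filters, 10 to 30 time steps, 15 to 20 epochs) -- problem sizes chosen
so the full suite runs comfortably on a single CPU while leaving every
claim intact.

## Saliency

`saliency_single()` computes `|d S_c / d input|`, the absolute gradient of
the class score with respect to the (standardized) input tensor -- the
first-order Taylor view of what the model attends to. The score is the
pre-softmax logit: softmax saturation would flatten the maps.
`average_features()` averages the `[60, 21, 6]` score array over the
feature axis to the `[60, 21]` channel-time map; `aggregate_maps()` takes
element-wise means across samples or subjects. Per-gesture aggregates use
correctly-classified samples where available. The linear discriminant is
not differentiable in this sense and is refused.

## Evaluation and statistics

`cross_validate()` runs trial-wise stratified k-fold (default 5): all
windows of one trial stay in one fold, folds are balanced per gesture, and
standardization is re-estimated inside each training fold -- no window
leakage. Rest-period samples stay with their preceding movement trial.
`compare_conditions()` bundles the study statistics: a paired Wilcoxon
signed-rank test of medium vs low density (exact p for small samples, zero
differences dropped, by the usual convention), a Friedman test across
decoders (df = decoders - 1), and Nemenyi pairwise p-values -- computed
from the studentized range distribution -- gated on Friedman significance
at 0.05. Fewer than six subjects triggers an underpowered warning but the
tests still run.

## The bundled experiments

Three study designs are packaged (`R/experiments.R`), fixed before any
results were read off, at scales a CPU handles in minutes:

* **Density** (`density_experiment`): 10 synthetic subjects (gain jitter
  ±10% emulates inter-subject variability), LDA decoder, 21-channel vs
  7-middle-channel montage, trial-wise 3-fold CV, paired Wilcoxon. The
  default activation patterns make the comparison informative (see above).
* **Spatial advantage** (`spatial_advantage_experiment`): class identity
  is a rotation of one spatial activation bump around the band, so classes
  differ *only* in where activity sits. The STCN is compared against the
  vanilla TCN in its channel-independent mode over 10 paired seeds,
  one-sided Wilcoxon. The channel-independent variant is the right
  baseline here: the flattened variant can read channel identity straight
  from its input layout, so only the channel-blind variant isolates the
  value of spatial feature *learning*. (The flattened mode remains the
  package default for ordinary decoding.)
* **Saliency recovery** (`saliency_recovery_experiment`): with known
  active channels per gesture, channel-mean saliency ranks of truly active
  channels are compared with inactive ones (Mann-Whitney, pooled over 10
  seeds).

`scripts/acceptance.R` re-runs all of these from scratch and writes the
resulting numbers as JSON.

## Numerical and degenerate-input conventions

* ms-to-sample conversion is `round()`, centralized in `window_spec()`.
* Recordings shorter than one window, non-positive durations, infeasible
  bands, baseline segments under 100 samples, and zero-variance baselines
  are errors; an SNR ratio at or below zero is a flagged sentinel.
* The LDA tie-break is the mean posterior; covariance singularity is
  handled by escalating shrinkage with a warning.
* Batch normalization uses eps 1e-5 and momentum 0.1; inference uses
  running statistics, so prediction is deterministic.
* The session container is a self-describing CSV (metadata header lines +
  `t,ch01..chNN,label` body) with 17-significant-digit doubles for
  bit-exact round trips; a plain CSV dialect with `t` in seconds is also
  read, inferring the sampling rate from the time column.

## Known limitations

The generator's phenomenological carrier cannot support claims about real
inter-subject variability, electrode shift, or fatigue. The network
architectures follow the published block structure but depth, width,
kernel sizes, merge rule and optimizer settings are this package's
defaults, not a reproduction of an exact (unpublished) configuration.
Accuracy figures obtained on synthetic cohorts are structural/directional
results (medium > low density; spatial model >= temporal model on
spatially-coded data), not predictions of accuracy on recorded data.
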