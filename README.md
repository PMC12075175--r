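# emgband

Gesture decoding for medium-density surface electromyography (EMG), with a
fully synthetic test bed.

Surface EMG armbands for myoelectric control usually carry either a handful
of electrodes (low density, limited spatial resolution) or large
high-density grids (impractical to wear). `emgband` implements the complete
decoding stack for the middle ground -- a ring of 7 sensor nodes x 3
channels = 21 channels sampled at 1,067 Hz -- and a labeled synthetic
session generator that emulates the cued recording protocol (six gesture
classes including rest, 10 repetitions, 6 s movement + 6 s rest per trial),
so every stage runs against known ground truth without hardware.

The stack:

* **Simulation** -- `emg_protocol()`, `emg_spatial_model()`,
  `generate_session()`: band-limited Gaussian carriers, node-correlated
  channels, gesture-specific spatial activation gains, per-channel SNR
  targets in the on/off variance-ratio sense.
* **Signal conditioning** -- `apply_filter_chain()`: 2nd-order Butterworth
  band-pass (30--350 Hz) + 50/60 Hz notch, zero-phase or causal;
  `segment_windows()`: overlapping 281.1 ms / 9.3 ms windows (300/10
  samples).
* **Activity detection** -- `detect_on_off()`, `compute_snr()`,
  `snr_report()`: double-threshold ON/OFF segmentation
  (`LT = mu_n + k1*sigma_n`, `UT = mu_n + k2*sigma_n`, minimum run length
  `m`) and per-channel `SNR = 10*log10(sigma_s^2/sigma_n^2 - 1)` in dB.
* **Features** -- `extract_feature_tensor()`: six time-domain descriptors
  per window per channel (integral square descriptor, its differences with
  the normalized root-square coefficients of the first/second derivative,
  mean log kernel, mean square root, mean second difference), tiled into a
  `[samples, 60 time steps, 21 channels, 6 features]` tensor.
* **Decoders** -- `fit_decoder(x, labels, kind = c("lda", "tcn", "stcn"))`:
  shrinkage-regularized LDA with per-sequence majority vote; a vanilla
  temporal convolutional network (causal dilated convolutions along time);
  and a simultaneous spatio-temporal convolutional network whose blocks
  convolve each input along time *and* across the (circular) channel axis
  in parallel. The networks -- including backpropagation and Adam -- are
  implemented natively in R; fits are bit-reproducible under a fixed seed.
* **Explanation** -- `saliency_single()`, `average_features()`,
  `aggregate_maps()`: absolute-gradient saliency of a class logit,
  averaged over the feature axis to `[60, 21]` channel-time maps.
* **Evaluation** -- `cross_validate()` (trial-wise stratified folds, no
  window leakage), `confusion()`, `compare_conditions()` (paired Wilcoxon
  signed-rank, Friedman, Nemenyi post-hoc).

## Worked example

```r
library(emgband)

protocol <- emg_protocol(reps_per_gesture = 3, move_s = 1.5, rest_s = 0.8,
                         seed = 31)
session  <- generate_session(protocol)
session
#> EMG recording: 44172 samples x 21 channels at 1067 Hz (41.4 s)
#>   labels: 1:4800 2:4800 3:4800 4:4800 5:4800 6:20172
#>   subject: S01  session: synthetic

head(snr_report(session), 3)
#>   channel   snr_db      e_n n_on n_off flagged
#> 1       1 7.192426 1.125692    3     4   FALSE
#> 2       2 3.143011 1.367457   16    17   FALSE
#> 3       3 7.825971 1.092934    3     4   FALSE

cv <- cross_validate(session, kind = "lda", density = "medium", k = 3,
                     time_steps = 10)
cv$accuracy
#> [1] 0.9885996
cv_low <- cross_validate(session, kind = "lda", density = "low", k = 3,
                         time_steps = 10)
cv_low$accuracy
#> [1] 0.796657
```

The 21-channel montage recovers the six gestures almost perfectly (98.9%),
while dropping to the 7 middle channels costs about 19 percentage points:
the default spatial model places part of the gesture contrast on the side
channels, which the low-density view cannot see. Per-channel SNR varies
with each channel's activation gains across the gesture set; a channel at
full gain for every movement would sit at the generator's 9.54 dB target.

For a trained network, saliency maps show *where* the model looks:

```r
rec <- apply_filter_chain(session)
wf  <- extract_feature_tensor(rec, window_spec(fs = protocol$fs),
                              time_steps = 10)
dec <- fit_decoder(wf, kind = "stcn",
                   config = stcn_config(n_blocks = 2, dilations = c(1, 2),
                                        filters = 8, epochs = 10),
                   seed = 1)
maps <- saliency_maps(dec, wf, gestures = 1)
maps[["power"]]
#> Saliency map [10 time steps x 21 channels], mean-over-samples, gesture 1
#>   top channels: 19, 1, 10
```

Saliency ranks the channels that *discriminate* the power grasp from the
other gestures -- here channel 1 (node 1, where its activation is
strongest) and channels where its spatial profile departs most from the
competing classes. The rigorous version of this check --
`saliency_recovery_experiment()`, where class identity sits in known
channels by construction -- is part of the test suite and the acceptance
script.

## Package layout

```
R/protocol.R      synthetic protocol, spatial model, session generator
R/recording.R     the emg_recording container, density selection
R/io.R            session CSV container (read/write, bit-exact round trip)
R/preprocess.R    filter chain, windowing
R/detect.R        double-threshold detection, SNR
R/features.R      descriptor features, feature tensor, standardization
R/nn.R            native convolutional-network engine (forward/backward)
R/decoders.R      fit_decoder(): LDA / TCN / STCN + predict methods
R/saliency.R      gradient saliency maps
R/evaluation.R    cross-validation, confusion, Wilcoxon/Friedman/Nemenyi
R/experiments.R   packaged study designs (density, spatial advantage,
                  saliency recovery)
R/pipeline.R      end-to-end pipeline with config, manifest, report
```

The methods vignette (`vignettes/emgband-methods.Rmd`) documents the
models, parameter choices and their rationale, the generator's scope, and
known limitations.
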