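Package: emgband
Title: Medium-Density Surface EMG Gesture Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, conditioning and decoding of medium-density (21-channel
    armband) surface electromyography for hand-gesture recognition. Provides a
    labeled synthetic session generator emulating a 7-node x 3-channel armband
    protocol, software emulation of the acquisition filter chain (Butterworth
    band-pass plus power-line notch), double-threshold muscle-activity detection
    with per-channel signal-to-noise ratio, six spatio-temporal descriptor
    features on overlapping windows, three gesture decoders (regularized linear
    discriminant analysis, a vanilla temporal convolutional network, and a
    simultaneous spatio-temporal convolutional network), gradient saliency maps
    over time and channels, and a cross-validated medium- versus low-density
    evaluation with nonparametric statistics (Wilcoxon, Friedman, Nemenyi).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
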