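Package: laminaPSTH
Title: Laminar Analysis of Stimulus-Evoked Cortical Spiking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing evoked multi-unit activity recorded with
    laminar (multi-contact) probes in somatosensory cortex: a synthetic-data
    generator with known ground truth (alternating-nerve stimulus trains,
    Poisson background and burst firing, stimulus-locked early and late
    evoked peaks, biphasic waveform templates rendered into continuous
    traces), zero-phase high-pass filtering and robust RMS-threshold spike
    detection, per-channel spike sorting on seven waveform features with
    PCA component selection and silhouette-selected k-means, peristimulus
    time histogram construction with background subtraction and peak
    amplitude and center-of-mass latency extraction, and layer-by-phase
    aggregation with baseline normalization and permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
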