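---
title: "Laminar analysis of stimulus-evoked cortical spiking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar analysis of stimulus-evoked cortical spiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(laminaPSTH)
```

## The analysis problem

laminaPSTH analyzes evoked multi-unit activity recorded with a penetrating
multi-contact (laminar) probe in primary somatosensory cortex (S1) while a
peripheral nerve is stimulated electrically. The experimental design it
targets is an acute nerve-injury preparation: two forelimb nerves (ulnar
and median) are stimulated in alternation, 200 pulses per session at a
nominal 2 Hz with randomized inter-stimulus intervals, one session every
10 min — three sessions before an intervention and eighteen after.
Each probe contact is assigned to a cortical layer (I–VI) from histology,
so the question "which layers become hyperexcitable after nerve injury,
and when?" can be answered by aggregating stimulus-locked responses over
group × layer × phase.

The chain implemented here is:

1. **Simulation** of stimulus schedules, spike trains, and continuous
   traces with known ground truth (`sim_config()`,
   `simulate_experiment()`, `generate_continuous()`).
2. **Detection**: zero-phase 300 Hz high-pass filtering and RMS-threshold
   spike detection with snippet extraction (`highpass_filter()`,
   `detect_spikes()`).
3. **Sorting**: seven waveform features per snippet, PCA with a
   10 %-variance retention rule, k-means with silhouette-selected cluster
   count capped at five (`snippet_features()`, `sort_channel()`).
4. **PSTH measures**: 1 ms-binned peristimulus time histograms from 50 ms
   before to 450 ms after each stimulus, background subtraction, peak
   amplitude, and center-of-mass (CoM) latency in an early (10–19 ms) and
   a late (21–35 ms) window (`build_psth()`, `subtract_background()`,
   `peak_amplitude()`, `center_of_mass()`).
5. **Aggregation**: exclusion of unresponsive channels, nerve pooling,
   30-min phase averaging, baseline normalization, and layer × phase
   summaries with SEMs (`exclude_unresponsive_channels()`,
   `pool_nerves()`, `normalize_to_baseline()`, `group_summary()`).

`run_pipeline()` chains all stages and writes CSV tables plus a
provenance JSON; `inst/scripts/laminar-pipeline.R` is a thin shell entry
point over it.

## What the simulator emulates — and what it does not

The generator's defaults encode the reference recording conditions: a
2-shank × 8-contact probe spanning layers I–VI (extra contacts in the
thick layers III and V), 25 kHz sampling, spontaneous Poisson firing well
below 10 spikes/s, occasional burst epochs (≤ 300 spikes/s) confined to
layers III–IV, and two stimulus-locked evoked components: an early peak
with latency Normal(15, 1) ms (Aβ-range afference) and a late peak at
Normal(26, 2) ms (Aδ range). Evoked spike counts are Poisson per stimulus
and channel — the maximum-entropy choice for count data — with per-layer
mean gains. Nerve injury is modelled as a multiplicative gain on the
early-peak mean from the first post-intervention session onward, by
default 1.46 in layer III, 1.20 in layer IV, and 1.17 in layers V–VI
(superficial layers unchanged), i.e. the strongest sensitization in
layer III.

Choices the reference conditions leave open, fixed here once:

* **Inter-stimulus jitter.** "Random inter-stimulus interval" without a
  stated law; we jitter each pulse uniformly by ±100 ms around its 500 ms
  grid position. This preserves the 2 Hz nominal rate, avoids entrainment,
  and keeps stimulus times strictly increasing.
* **Per-layer evoked gains.** Only indirectly constrained by reported
  peak firing rates (up to ~740 spikes/s); defaults of 0.2–1.8 expected
  early spikes per stimulus reproduce that range and are tunable.
* **Unit structure.** Three units per channel (recordings reported 1–3),
  with a 1 ms per-unit absolute refractory period — a physiological floor
  rather than a reported value. Spikes are assigned to a non-refractory
  unit of their channel, so the multi-unit stream loses a spike only when
  every unit is refractory; this keeps planted multiplicative gains
  recoverable instead of being censored by coincidence losses.
* **Waveform templates.** Biphasic difference-of-Gaussians shapes,
  larger in layers I–II (qualitative match to reported spike amplitudes);
  exact shapes are free parameters.

The simulator does **not** model anesthetic-depth drift (a known slow
confound in long sessions), LFP/CSD structure, electrode drift, or
biophysical neuron dynamics. Passing recovery tests therefore shows the
analysis code is correct and unbiased under the stated statistical
assumptions — not that those assumptions exhaust real recordings.

## Detection

Offline re-analysis filters with a zero-phase (forward–backward)
Butterworth high-pass at 300 Hz. Zero-phase filtering preserves evoked
latencies; an online acquisition chain uses a causal filter, so absolute
latencies from re-detected data can differ from online-detected ones by
a fraction of a millisecond — a documented divergence.

The detection threshold is `k_rms` (3–5, default 4) times a robust noise
estimate, `median(|x|)/0.6745`. The raw RMS would be inflated by the
spikes themselves; the median-based estimate tracks the background noise
SD to a few percent even with large spikes embedded. Events are
negative-going crossings (the dominant polarity of somatic extracellular
spikes; configurable), separated by a 1 ms dead time, each yielding a
0.6 ms/1.2 ms pre/post snippet (46 samples at 25 kHz, crossing at sample
16). Snippet windows that would leave the trace drop the event with a
warning and a logged count.

## Sorting

Per channel, each snippet is reduced to seven descriptors: number of
zero crossings, width (FWHM) of the most prominent peak, amplitude and
latency of the positive and negative extrema, and whether the negative
polarity leads. Two numerical choices matter:

* "Most prominent" is resolved as the extremum of largest absolute
  amplitude (the topographic-prominence alternative is not used).
* Peak amplitudes and latencies are refined by parabolic sub-sample
  interpolation around the extremum. Without it, latencies are quantized
  to the sample grid; after standardization a near-constant quantized
  feature collapses into a handful of exact atoms, and k-means plus
  silhouette will happily "discover" those atoms as clusters. Sub-sample
  interpolation removes the artifact at its source.

Features are standardized (their units are incommensurable: counts, ms,
µV, a binary flag; constant features are dropped), principal components
explaining more than 10 % of the variance are retained, and k-means
(10 restarts) is run for k = 2..5 — a cap of five, since few units per
channel are expected. The k with the highest mean silhouette wins, ties
going to the smaller k; if the best silhouette is below 0.25 the channel
is treated as a single unit (k = 1 must be reachable, and the silhouette
is undefined there). A channel with fewer than 10 snippets is not split.

A known limitation follows from standardization: a feature that carries
no between-unit structure is still rescaled to unit variance and dilutes
the silhouette contrast, which can bias the selected k upward when such
features dominate. With the seven waveform features this matters little
in practice because distinct units differ along several features at
once, but it is the reason recovery benchmarks plant units that differ
in amplitude, width, and rebound shape rather than along a single axis.

## PSTH measures

Bins are 1 ms wide and centred on integer millisecond labels: bin *b*
covers [*b* − 0.5, *b* + 0.5) ms, 500 bins labelled −50..449. With the
windows addressing inclusive labels (early 10..19, late 21..35,
background −50..−5), a centred bin makes the binned latency estimator
unbiased: counts of spikes with latency Normal(15, 1) have their mass
centred on bin 15, and the window CoM recovers 15.0 ms. A left-edge
convention ([*b*, *b* + 1)) would bias every CoM by −0.5 ms, which is
why it is not used.

Background is subtracted as the mean per-bin count over the −50..−5 ms
window (this compensates for threshold differences across channels);
counts may then be negative. Peak amplitude is the window maximum of the
background-subtracted histogram. The CoM is the spike-count-weighted
mean of bin times; on subtracted histograms negative bins are clipped to
zero by default, since negative weights would break the weighted-mean
semantics (a switch allows raw counts). A window with no spike mass has
an undefined CoM, which propagates as `NA` and is excluded from
aggregation with a logged count.

Sessions are grouped three per 30-min phase (phase 0 = baseline). Within
a phase the three session PSTHs are averaged per channel and nerve, and
measures are extracted from the phase average. Because both background
subtraction and averaging are linear, subtract-then-average equals
average-then-subtract (verified numerically in the tests). Measures are
extracted per channel and then averaged — not extracted from an average
PSTH across channels — so that layer assignment stays meaningful.

Latency converts to conduction velocity as distance/(latency − offset),
with the non-conduction (synaptic/central) delay defaulting to 0 and the
nerve-path distance supplied by the user; a 15 ms early latency over
0.9 m gives 60 m/s, in the Aβ range.

## Aggregation

A channel is excluded only if it never responds: in no session does its
raw early- or late-window peak exceed the pre-stimulus background mean
by more than 3 background SDs (the criterion constant is configurable;
no formula was stated for the original exclusions). Ulnar and median
measurements are averaged per channel × phase × window. Baseline
normalization expresses each phase as a percentage of the same channel's
phase-0 value; a non-positive baseline flags the channel's values as
missing rather than producing unstable ratios. Summaries report cell
means, SEM = sd/√n, and n, with channels as the unit for layer-resolved
cells and equal weighting of channels within a cell. Formal
repeated-measures or mixed-model inference is out of scope; a two-sided
permutation test for a difference in cell means (add-one estimator, so
p ∈ (0, 1] and super-uniform under the null) is provided as a
descriptive companion.

## Problem sizes and determinism

All empirical properties asserted by the test suite are computed at desk
scale, chosen as the smallest sizes at which the binomial/Poisson noise
of the property is far from its acceptance margin: detection fidelity on
4 channels × 10 s of 25 kHz trace at SNR 8; sorting recovery over 50
channels × 120–180 snippets; latency and injury-gain recovery over 20
simulated experiments of 3 + 6 sessions × 200 stimuli; and a full
21-session default pipeline run. Every stochastic stage takes an explicit
seed, RNG state is restored after use, and a fixed seed makes the whole
pipeline byte-identical across runs, which the tests assert.

```{r example}
cfg <- sim_config(seed = 1, n_channels = 4,
                  layer_of_channel = c("III", "III", "IV", "IV"),
                  sessions_pre = 3, sessions_post = 6, burst_rate = 0)
ex <- simulate_experiment(cfg)
psths <- lapply(session_psths(ex$spikes, ex$schedule), subtract_background)
meas <- psth_measurements(phase_average_psths(psths),
                          windows = analysis_windows()["early"])
normed <- normalize_to_baseline(pool_nerves(meas))
normed$layer <- cfg$layer_of_channel[normed$channel]
group_summary(normed[normed$phase > 0, ], "amplitude_pct", "layer")
```

The layer III post-injury mean lands near the planted 146 % and layer IV
near 120 %; each cell pools two channels over two post-intervention
phases.

## Known limitations

* The silhouette-selected k is sensitive to uninformative features (see
  above); on noisy real snippets the sorter tends to over-split rather
  than merge. Headline PSTH measures are computed from all threshold
  crossings per channel, so sorting quality does not propagate into
  them.
* "Estimated marginal means" are approximated by plain cell means, which
  coincide only on (near-)balanced designs such as the simulated ones.
* The exclusion rule, jitter law, and per-layer gain magnitudes are
  package choices where the reference conditions are silent; all are
  exposed as parameters.
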