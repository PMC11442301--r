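# laminaPSTH

Laminar analysis of stimulus-evoked cortical spiking in R.

`laminaPSTH` implements the analysis chain used to quantify somatosensory
cortex (S1) excitability from penetrating multi-contact ("laminar") probe
recordings during repeated peripheral nerve stimulation — the setting of
acute nerve-injury electrophysiology, where two forelimb nerves are
stimulated in alternation (200 pulses per session at a nominal 2 Hz,
sessions every 10 min, 3 before and 18 after an intervention) and each
probe contact is assigned to a cortical layer (I–VI) from histology.

The package covers, as tested reusable functions:

* **Synthetic data with ground truth** — stimulus schedules with
  alternating nerves and jittered intervals; background Poisson firing
  with layer III–IV burst epochs; stimulus-locked early (~15 ms, Aβ) and
  late (~26 ms, Aδ) evoked peaks with per-layer gains; a post-injury
  multiplicative gain on the early peak (default ×1.46 in layer III,
  ×1.20 in layer IV); biphasic waveform templates rendered into
  continuous 25 kHz traces.
* **Spike detection** — zero-phase 300 Hz high-pass filtering, thresholds
  at 3–5× a robust (median-based) RMS noise estimate, dead time, snippet
  extraction.
* **Spike sorting** — seven waveform descriptors per snippet, PCA with a
  10 %-explained-variance retention rule, k-means with
  silhouette-selected cluster count capped at five.
* **PSTH measures** — 1 ms bins from −50 to +450 ms around each stimulus;
  background subtraction over the −50..−5 ms window; peak amplitude
  (window maximum, spikes/bin) and center-of-mass latency

  CoM = Σ<sub>t1..t2</sub>(spikes × t) / Σ<sub>t1..t2</sub> spikes

  in the early (10–19 ms) and late (21–35 ms) windows; conversion of
  latency to conduction velocity.
* **Laminar aggregation** — exclusion of never-responsive channels, nerve
  pooling, 30-min phase averaging (3 sessions/phase), normalization to
  the pre-intervention baseline, group × layer × phase means ± SEM, and a
  permutation test for cell differences.

`run_pipeline()` chains everything and writes CSV tables plus a
provenance JSON; `inst/scripts/laminar-pipeline.R` is a shell entry
point.

## Worked example

Simulate a four-channel experiment (two contacts in layer III, two in
layer IV; 3 baseline and 6 post-injury sessions), build per-session
PSTHs, average them into 30-min phases, extract early-window peak
amplitudes, pool the two nerves, normalize to baseline, and summarize by
layer:

```r
library(laminaPSTH)

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
#>   layer     mean      sem n
#> 1   III 147.2812 5.531630 4
#> 2    IV 120.7940 4.041658 4
```

The post-injury early-peak amplitude in layer III is recovered at ~147 %
of baseline (planted gain: 146 %) and layer IV at ~121 % (planted:
120 %); `n` counts channel × phase cells and `sem` is sd/√n. The same
simulated experiment carries its ground truth (`ex$ground_truth`), so
recovery can be scored exactly.

A full default run (16 channels spanning layers I–VI, 21 sessions, plus
a short continuous-trace segment that exercises detection and sorting):

```r
run_pipeline(run_config(seed = 1), "out/")
```

writes `stimulus_events.csv`, `spike_events.csv`, `detected_events.csv`,
`sorting_report.csv`, `psth_measurements.csv`,
`normalized_measurements.csv`, `layer_phase_summary.csv`, a provenance
JSON, and a log.

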