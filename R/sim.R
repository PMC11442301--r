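#' Simulation configuration for a laminar evoked-response experiment
#'
#' Builds the parameter set for the synthetic-data generator. Defaults
#' emulate an acute recording from pig primary somatosensory cortex with a
#' two-shank, 16-contact penetrating probe spanning cortical layers I-VI:
#' trains of 200 electrical stimuli per session delivered at a nominal 2 Hz
#' with random inter-stimulus jitter, alternating between the ulnar and
#' median nerves (100 pulses per nerve per session); sessions repeated every
#' 10 min, 3 before and 18 after an intervention; low spontaneous firing
#' (< 10 spikes/s) with occasional bursts confined to layers III-IV; and
#' stimulus-locked evoked peaks near 15 ms (A-beta) and 26 ms (A-delta).
#' A nerve-injury intervention is modelled as a multiplicative gain on the
#' early evoked peak from the first post-intervention session onward,
#' largest in layer III.
#'
#' @param seed integer seed controlling all randomness downstream.
#' @param n_channels number of recording channels.
#' @param layer_of_channel character vector of layer labels ("I".."VI"),
#'   one per channel. The default lays out two identical shanks running
#'   from layer I (superficial) to layer VI (deep), with extra contacts in
#'   the thick layers III and V.
#' @param sampling_rate sampling rate in Hz for continuous traces.
#' @param sessions_pre,sessions_post number of stimulation sessions before
#'   and after the intervention.
#' @param stimuli_per_session stimuli per session (both nerves together).
#' @param stim_rate nominal stimulation rate in Hz.
#' @param isi_jitter_ms half-width (ms) of the uniform jitter added to each
#'   stimulus time around its nominal grid position.
#' @param session_interval_s start-to-start spacing of sessions in seconds.
#' @param background_rate spontaneous firing rate per channel (spikes/s).
#' @param burst_rate rate (1/s) at which burst epochs start on channels in
#'   layers III-IV; set to 0 to disable bursts.
#' @param burst_duration_s mean duration of a burst epoch (gamma
#'   distributed, shape 2).
#' @param burst_peak_rate firing rate (spikes/s) inside a burst epoch.
#' @param early_latency_mean,early_latency_sd mean and SD (ms) of the early
#'   evoked-spike latency.
#' @param late_latency_mean,late_latency_sd mean and SD (ms) of the late
#'   evoked-spike latency.
#' @param early_gain_by_layer,late_gain_by_layer named numeric vectors
#'   (names "I".."VI"): expected evoked spikes per stimulus per channel for
#'   the early and late response.
#' @param injury_effect_by_layer named numeric vector: multiplicative gain
#'   applied to the early evoked response in post-intervention sessions.
#' @param noise_sd additive Gaussian noise SD (uV) for continuous traces.
#' @param units_per_channel number of distinct units planted per channel
#'   (1-5).
#' @param refractory_ms per-unit absolute refractory period (ms).
#' @param sessions_per_phase sessions grouped into one 30-min analysis
#'   phase.
#'
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_channels = 16L,
                       layer_of_channel = default_probe_layers(n_channels),
                       sampling_rate = 25000,
                       sessions_pre = 3L,
                       sessions_post = 18L,
                       stimuli_per_session = 200L,
                       stim_rate = 2,
                       isi_jitter_ms = 100,
                       session_interval_s = 600,
                       background_rate = 5,
                       burst_rate = 0.02,
                       burst_duration_s = 0.15,
                       burst_peak_rate = 250,
                       early_latency_mean = 15, early_latency_sd = 1,
                       late_latency_mean = 26, late_latency_sd = 2,
                       early_gain_by_layer = c(I = 0.2, II = 0.5, III = 1.5,
                                               IV = 1.8, V = 1.2, VI = 1.0),
                       late_gain_by_layer = c(I = 0.1, II = 0.3, III = 0.8,
                                              IV = 0.5, V = 0.4, VI = 0.3),
                       injury_effect_by_layer = c(I = 1, II = 1, III = 1.46,
                                                  IV = 1.20, V = 1.17,
                                                  VI = 1.17),
                       noise_sd = 10,
                       units_per_channel = 3L,
                       refractory_ms = 1,
                       sessions_per_phase = 3L) {
  # tolerate list-valued fields (e.g. parsed from YAML)
  early_gain_by_layer <- unlist(early_gain_by_layer)
  late_gain_by_layer <- unlist(late_gain_by_layer)
  injury_effect_by_layer <- unlist(injury_effect_by_layer)
  cfg <- list(seed = as.integer(seed),
              n_channels = as.integer(n_channels),
              layer_of_channel = as.character(unlist(layer_of_channel)),
              sampling_rate = sampling_rate,
              sessions_pre = as.integer(sessions_pre),
              sessions_post = as.integer(sessions_post),
              stimuli_per_session = as.integer(stimuli_per_session),
              stim_rate = stim_rate,
              isi_jitter_ms = isi_jitter_ms,
              session_interval_s = session_interval_s,
              background_rate = background_rate,
              burst_rate = burst_rate,
              burst_duration_s = burst_duration_s,
              burst_peak_rate = burst_peak_rate,
              early_latency_mean = early_latency_mean,
              early_latency_sd = early_latency_sd,
              late_latency_mean = late_latency_mean,
              late_latency_sd = late_latency_sd,
              early_gain_by_layer = early_gain_by_layer,
              late_gain_by_layer = late_gain_by_layer,
              injury_effect_by_layer = injury_effect_by_layer,
              noise_sd = noise_sd,
              units_per_channel = as.integer(units_per_channel),
              refractory_ms = refractory_ms,
              sessions_per_phase = as.integer(sessions_per_phase))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default laminar layout of a two-shank, eight-contact-per-shank probe
#'
#' Contacts run from superficial to deep on each shank; layers III and V
#' receive two contacts each, reflecting their thickness.
#'
#' @param n_channels total number of channels (multiple of 8 uses the
#'   per-shank pattern; otherwise the pattern is recycled).
#' @return character vector of layer labels.
#' @export
default_probe_layers <- function(n_channels = 16L) {
  shank <- c("I", "II", "III", "III", "IV", "V", "V", "VI")
  rep_len(shank, n_channels)
}

cortical_layers <- function() c("I", "II", "III", "IV", "V", "VI")

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$sampling_rate <= 0) stop("invalid config: sampling_rate must be > 0")
  if (cfg$stim_rate <= 0) stop("invalid config: stim_rate must be > 0")
  if (cfg$stimuli_per_session <= 0)
    stop("invalid config: stimuli_per_session must be > 0")
  if (length(cfg$layer_of_channel) != cfg$n_channels)
    stop("invalid config: layer_of_channel must have one label per channel")
  if (!all(cfg$layer_of_channel %in% cortical_layers()))
    stop("invalid config: layer labels must be in I..VI")
  num_nonneg <- c("isi_jitter_ms", "background_rate", "burst_rate",
                  "burst_duration_s", "burst_peak_rate", "early_latency_sd",
                  "late_latency_sd", "noise_sd", "refractory_ms")
  for (nm in num_nonneg)
    if (any(cfg[[nm]] < 0)) stop("invalid config: ", nm, " must be >= 0")
  for (nm in c("early_gain_by_layer", "late_gain_by_layer",
               "injury_effect_by_layer")) {
    v <- cfg[[nm]]
    if (any(v < 0)) stop("invalid config: ", nm, " must be >= 0")
    if (!all(cortical_layers() %in% names(v)))
      stop("invalid config: ", nm, " must name all layers I..VI")
  }
  if (cfg$sessions_pre < 0 || cfg$sessions_post < 0)
    stop("invalid config: session counts must be >= 0")
  if (cfg$units_per_channel < 1 || cfg$units_per_channel > 5)
    stop("invalid config: units_per_channel must be in 1..5")
  invisible(cfg)
}

# Run code under a given seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a stimulus schedule
#'
#' Produces the full train of stimulus events for an experiment: per
#' session, \code{stimuli_per_session} pulses alternating between the ulnar
#' and median nerve at a nominal rate of \code{stim_rate} Hz, each pulse
#' jittered uniformly by up to \code{isi_jitter_ms} around its nominal grid
#' time to avoid entrainment. Sessions start \code{session_interval_s}
#' apart; the first \code{sessions_pre} sessions are flagged
#' pre-intervention (phase 0), post-intervention sessions are grouped into
#' phases of \code{sessions_per_phase}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed seed for the jitter draw; defaults to \code{config$seed}.
#' @return data.frame with columns \code{time_s}, \code{nerve}
#'   ("ulnar"/"median"), \code{session}, \code{phase}, \code{pre}.
#' @export
generate_stimulus_schedule <- function(config, seed = config$seed) {
  validate_sim_config(config)
  n_sessions <- config$sessions_pre + config$sessions_post
  if (n_sessions == 0L)
    return(data.frame(time_s = numeric(0), nerve = character(0),
                      session = integer(0), phase = integer(0),
                      pre = logical(0)))
  ph <- phase_schedule(config$sessions_pre, config$sessions_post,
                       config$sessions_per_phase)
  n <- config$stimuli_per_session
  isi <- 1 / config$stim_rate
  jit_s <- config$isi_jitter_ms / 1000
  with_local_seed(seed, {
    out <- lapply(seq_len(n_sessions), function(s) {
      t0 <- (s - 1) * config$session_interval_s
      nominal <- t0 + (seq_len(n) - 1) * isi
      jitter <- if (jit_s > 0) stats::runif(n, -jit_s, jit_s) else 0
      data.frame(time_s = nominal + jitter,
                 nerve = rep_len(c("ulnar", "median"), n),
                 session = s,
                 phase = ph$phase[s],
                 pre = ph$phase[s] == 0L)
    })
    do.call(rbind, out)
  })
}

#' Generate background and stimulus-evoked spike trains
#'
#' Background activity is a homogeneous Poisson process per channel at
#' \code{background_rate}, running for the duration of each stimulation
#' session, plus (for channels in layers III-IV) burst epochs with
#' gamma-distributed durations during which the rate is elevated to
#' \code{burst_peak_rate}. Evoked activity adds, per stimulus and channel,
#' a Poisson-distributed number of spikes at latencies drawn from
#' Normal(early_latency_mean, early_latency_sd) and analogously for the
#' late peak; in post-intervention sessions the early-peak mean count is
#' multiplied by the layer's \code{injury_effect_by_layer}. Spikes are
#' divided among the channel's planted units and a per-unit absolute
#' refractory period is enforced by thinning.
#'
#' @param config a \code{\link{sim_config}}.
#' @param schedule stimulus schedule from
#'   \code{\link{generate_stimulus_schedule}}; may have zero rows for a
#'   background-only simulation, in which case \code{duration_s} is
#'   required.
#' @param duration_s duration of a background-only simulation (s).
#' @param seed seed; defaults to \code{config$seed + 1}.
#' @return list with elements \code{spikes} (data.frame: \code{time_s},
#'   \code{channel}, \code{unit}, \code{session}, \code{phase},
#'   \code{nerve}, \code{source}) sorted by time, and \code{ground_truth}
#'   (unit map, planted gains/latencies, per-stimulus evoked counts).
#' @export
generate_spike_trains <- function(config, schedule, duration_s = NULL,
                                  seed = config$seed + 1L) {
  validate_sim_config(config)
  if ((is.null(schedule) || nrow(schedule) == 0) && is.null(duration_s))
    stop("schedule is empty: supply duration_s for a background-only run")
  nch <- config$n_channels
  upc <- config$units_per_channel
  unit_map <- data.frame(unit = seq_len(nch * upc),
                         channel = rep(seq_len(nch), each = upc),
                         layer = rep(config$layer_of_channel, each = upc))

  # session windows over which background activity is simulated
  if (!is.null(schedule) && nrow(schedule) > 0) {
    sess <- split(schedule$time_s, schedule$session)
    windows <- data.frame(session = as.integer(names(sess)),
                          t0 = vapply(sess, min, 0) - 1,
                          t1 = vapply(sess, max, 0) + 1)
  } else {
    windows <- data.frame(session = 1L, t0 = 0, t1 = duration_s)
  }

  with_local_seed(seed, {
    parts <- list()

    ## background (+ bursts in layers III-IV)
    for (w in seq_len(nrow(windows))) {
      dur <- windows$t1[w] - windows$t0[w]
      for (ch in seq_len(nch)) {
        n_bg <- stats::rpois(1, config$background_rate * dur)
        t_bg <- if (n_bg > 0) windows$t0[w] + stats::runif(n_bg) * dur
                else numeric(0)
        t_burst <- numeric(0)
        if (config$burst_rate > 0 &&
            config$layer_of_channel[ch] %in% c("III", "IV")) {
          n_ep <- stats::rpois(1, config$burst_rate * dur)
          if (n_ep > 0) {
            starts <- windows$t0[w] + stats::runif(n_ep) * dur
            lens <- stats::rgamma(n_ep, shape = 2,
                                  scale = config$burst_duration_s / 2)
            extra <- max(config$burst_peak_rate - config$background_rate, 0)
            for (e in seq_len(n_ep)) {
              nb <- stats::rpois(1, extra * lens[e])
              if (nb > 0)
                t_burst <- c(t_burst, starts[e] + stats::runif(nb) * lens[e])
            }
          }
        }
        tt <- c(t_bg, t_burst)
        if (length(tt))
          parts[[length(parts) + 1L]] <- data.frame(
            time_s = tt, channel = ch,
            session = windows$session[w], phase = NA_integer_,
            nerve = NA_character_,
            source = rep(c("background", "burst"),
                         c(length(t_bg), length(t_burst))))
      }
    }

    ## evoked responses
    evoked_counts <- NULL
    if (!is.null(schedule) && nrow(schedule) > 0) {
      ns <- nrow(schedule)
      layer <- config$layer_of_channel
      for (ch in seq_len(nch)) {
        g_early <- config$early_gain_by_layer[[layer[ch]]]
        g_late <- config$late_gain_by_layer[[layer[ch]]]
        mult <- ifelse(schedule$pre, 1,
                       config$injury_effect_by_layer[[layer[ch]]])
        n_early <- stats::rpois(ns, g_early * mult)
        n_late <- stats::rpois(ns, g_late)
        idx_e <- rep.int(seq_len(ns), n_early)
        idx_l <- rep.int(seq_len(ns), n_late)
        t_e <- schedule$time_s[idx_e] +
          stats::rnorm(length(idx_e), config$early_latency_mean,
                       config$early_latency_sd) / 1000
        t_l <- schedule$time_s[idx_l] +
          stats::rnorm(length(idx_l), config$late_latency_mean,
                       config$late_latency_sd) / 1000
        if (length(idx_e) + length(idx_l) > 0)
          parts[[length(parts) + 1L]] <- data.frame(
            time_s = c(t_e, t_l), channel = ch,
            session = schedule$session[c(idx_e, idx_l)],
            phase = schedule$phase[c(idx_e, idx_l)],
            nerve = schedule$nerve[c(idx_e, idx_l)],
            source = rep(c("early", "late"),
                         c(length(idx_e), length(idx_l))))
        evoked_counts <- rbind(evoked_counts, data.frame(
          channel = ch, stimulus = seq_len(ns),
          session = schedule$session, phase = schedule$phase,
          nerve = schedule$nerve, n_early = n_early, n_late = n_late))
      }
    }

    spikes <- if (length(parts)) do.call(rbind, parts)
              else data.frame(time_s = numeric(0), channel = integer(0),
                              session = integer(0), phase = integer(0),
                              nerve = character(0), source = character(0))

    # assign spikes to the channel's units honouring each unit's
    # refractory period; a spike is lost only if every unit on the
    # channel is refractory (the trace is multi-unit activity)
    if (nrow(spikes)) {
      spikes <- spikes[order(spikes$time_s), , drop = FALSE]
      spikes$unit <- assign_units_refractory(spikes$time_s, spikes$channel,
                                             upc,
                                             config$refractory_ms / 1000)
      spikes <- spikes[!is.na(spikes$unit), , drop = FALSE]
      rownames(spikes) <- NULL
    } else {
      spikes$unit <- integer(0)
    }
    spikes <- spikes[, c("time_s", "channel", "unit", "session", "phase",
                         "nerve", "source")]

    list(spikes = spikes,
         ground_truth = list(
           unit_map = unit_map,
           evoked_counts = evoked_counts,
           planted = list(
             early_latency_mean = config$early_latency_mean,
             early_latency_sd = config$early_latency_sd,
             late_latency_mean = config$late_latency_mean,
             late_latency_sd = config$late_latency_sd,
             early_gain_by_layer = config$early_gain_by_layer,
             late_gain_by_layer = config$late_gain_by_layer,
             injury_effect_by_layer = config$injury_effect_by_layer)))
  })
}

# Assign time-ordered spikes to units (one block of `upc` unit ids per
# channel), drawing uniformly among the units of the spike's channel that
# are past their refractory period; NA when none is available.
assign_units_refractory <- function(time_s, channel, upc, refractory_s) {
  n <- length(time_s)
  unit <- rep(NA_integer_, n)
  last <- new.env(parent = emptyenv())
  for (ch in unique(channel)) {
    idx <- which(channel == ch)
    tu <- time_s[idx]
    last_fire <- rep(-Inf, upc)
    pick <- integer(length(tu))
    for (i in seq_along(tu)) {
      free <- which(tu[i] - last_fire >= refractory_s)
      if (length(free) == 0) { pick[i] <- NA_integer_; next }
      u <- if (length(free) == 1) free else
        free[sample.int(length(free), 1)]
      last_fire[u] <- tu[i]
      pick[i] <- u
    }
    unit[idx] <- (ch - 1L) * upc + pick
  }
  unit
}

#' Biphasic extracellular waveform template
#'
#' Difference-of-Gaussians template: a sharp negative deflection followed
#' by a broader positive rebound, the canonical shape of a somatic
#' extracellular spike. The returned vector carries attributes
#' \code{peak_index} (sample of the negative peak) and \code{sampling_rate}.
#'
#' @param sampling_rate Hz.
#' @param neg_amp negative peak amplitude in uV (given as a positive
#'   magnitude).
#' @param pos_amp positive rebound amplitude in uV.
#' @param neg_sd_ms,pos_sd_ms Gaussian widths (ms) of the two lobes.
#' @param pos_delay_ms delay (ms) of the positive lobe after the negative
#'   peak.
#' @param span_ms template support before/after the negative peak (ms).
#' @return numeric vector of template samples (uV).
#' @export
waveform_template <- function(sampling_rate = 25000, neg_amp = 80,
                              pos_amp = 30, neg_sd_ms = 0.1,
                              pos_sd_ms = 0.25, pos_delay_ms = 0.45,
                              span_ms = c(0.6, 1.4)) {
  t_ms <- seq(-span_ms[1], span_ms[2], by = 1000 / sampling_rate)
  w <- -neg_amp * exp(-t_ms^2 / (2 * neg_sd_ms^2)) +
    pos_amp * exp(-(t_ms - pos_delay_ms)^2 / (2 * pos_sd_ms^2))
  structure(w, peak_index = which.min(abs(t_ms)),
            sampling_rate = sampling_rate)
}

# Per-unit templates: spikes in superficial layers (I-II) are larger, and
# units on the same channel differ in amplitude and rebound shape so the
# waveform features can distinguish them.
default_unit_templates <- function(config) {
  upc <- config$units_per_channel
  out <- list()
  for (ch in seq_len(config$n_channels)) {
    base <- if (config$layer_of_channel[ch] %in% c("I", "II")) 140 else 90
    for (u in seq_len(upc)) {
      amp <- base * (1 + 0.6 * (u - 1))
      out[[(ch - 1L) * upc + u]] <- waveform_template(
        sampling_rate = config$sampling_rate,
        neg_amp = amp, pos_amp = 0.35 * amp,
        neg_sd_ms = 0.08 + 0.03 * (u - 1),
        pos_sd_ms = 0.2 + 0.1 * (u - 1),
        pos_delay_ms = 0.4 + 0.15 * (u - 1))
    }
  }
  out
}

#' Render spike trains into a continuous voltage recording
#'
#' Places each unit's waveform template at its spike times (negative peak
#' aligned to the spike time), sums overlapping templates linearly, and
#' adds white Gaussian noise of SD \code{config$noise_sd}.
#'
#' @param config a \code{\link{sim_config}}.
#' @param spikes spike data.frame as produced by
#'   \code{\link{generate_spike_trains}} (columns \code{time_s},
#'   \code{channel}, \code{unit}).
#' @param duration_s trace duration; defaults to last spike + 5 ms.
#' @param t_start_s recording start time; spike times are interpreted
#'   relative to the same clock.
#' @param templates optional list of per-unit templates (uV), indexed by
#'   unit id; defaults to \code{default_unit_templates(config)}.
#' @param seed seed for the noise draw; defaults to \code{config$seed + 2}.
#' @return object of class \code{"continuous_recording"}: list with
#'   \code{samples} (n_samples x n_channels matrix, uV),
#'   \code{sampling_rate}, \code{t_start_s}, and \code{probe} metadata.
#' @export
generate_continuous <- function(config, spikes, duration_s = NULL,
                                t_start_s = 0, templates = NULL,
                                seed = config$seed + 2L) {
  validate_sim_config(config)
  if (is.null(templates)) templates <- default_unit_templates(config)
  fs <- config$sampling_rate
  if (is.null(duration_s)) {
    duration_s <- if (nrow(spikes)) max(spikes$time_s) - t_start_s + 0.005
                  else 1
  }
  n <- round(duration_s * fs)
  x <- matrix(0, nrow = n, ncol = config$n_channels)
  if (nrow(spikes)) {
    if (any(spikes$time_s < t_start_s) ||
        any(spikes$time_s > t_start_s + duration_s))
      stop("spike beyond trace duration")
    for (i in seq_len(nrow(spikes))) {
      tpl <- templates[[spikes$unit[i]]]
      pk <- attr(tpl, "peak_index")
      i0 <- round((spikes$time_s[i] - t_start_s) * fs) + 1L - (pk - 1L)
      idx <- i0:(i0 + length(tpl) - 1L)
      ok <- idx >= 1L & idx <= n
      x[idx[ok], spikes$channel[i]] <- x[idx[ok], spikes$channel[i]] +
        tpl[ok]
    }
  }
  if (config$noise_sd > 0)
    x <- x + with_local_seed(seed,
      matrix(stats::rnorm(n * config$n_channels, 0, config$noise_sd),
             nrow = n))
  new_continuous_recording(x, fs, t_start_s,
                           probe = data.frame(
                             channel = seq_len(config$n_channels),
                             shank = ((seq_len(config$n_channels) - 1) %/% 8) + 1,
                             layer = config$layer_of_channel))
}

new_continuous_recording <- function(samples, sampling_rate, t_start_s = 0,
                                     probe = NULL, filtered = FALSE) {
  stopifnot(is.matrix(samples), sampling_rate > 0)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 t_start_s = t_start_s, probe = probe, filtered = filtered),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("continuous_recording: %d channels x %d samples @ %g Hz (%s)\n",
              ncol(x$samples), nrow(x$samples), x$sampling_rate,
              if (isTRUE(x$filtered)) "high-pass filtered" else "raw"))
  invisible(x)
}

#' Simulate a full experiment (schedule plus spike trains)
#'
#' Convenience wrapper running \code{\link{generate_stimulus_schedule}} and
#' \code{\link{generate_spike_trains}} under the configuration's seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{schedule}, \code{spikes}, \code{ground_truth}.
#' @export
simulate_experiment <- function(config) {
  schedule <- generate_stimulus_schedule(config)
  tr <- generate_spike_trains(config, schedule)
  list(schedule = schedule, spikes = tr$spikes,
       ground_truth = tr$ground_truth)
}
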