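#' Pipeline run configuration
#'
#' Assembles every tunable of the analysis chain with defaults matching
#' the reference acquisition and analysis settings: 25 kHz sampling,
#' 300 Hz high-pass, detection at 4x robust RMS, 1 ms PSTH bins spanning
#' -50..450 ms, early/late windows 10-19 / 21-35 ms, background window
#' -50..-5 ms, 3 pre- and 18 post-intervention sessions grouped three per
#' 30-min phase.
#'
#' @param mode "simulate+analyze" (default), "simulate", or "analyze".
#' @param seed integer master seed for the run.
#' @param sim list of overrides passed to \code{\link{sim_config}}.
#' @param detection list: \code{highpass_hz}, \code{order}, \code{k_rms},
#'   \code{dead_time_ms}, \code{pre_ms}, \code{post_ms}.
#' @param sorting list: \code{max_k}, \code{k1_threshold},
#'   \code{min_snippets}, \code{restarts}, \code{var_threshold}.
#' @param psth list: \code{t_pre_ms}, \code{t_post_ms}, \code{early},
#'   \code{late}, \code{background}.
#' @param aggregation list: \code{c_sd} (responsiveness criterion in
#'   background SDs).
#' @param continuous_demo_s seconds of continuous trace synthesized from
#'   the start of the first session to exercise the detection and sorting
#'   stages (0 disables that stage in simulate mode).
#' @param group group label attached to summaries (e.g. "NI" or
#'   "control").
#' @param paths named list of input paths for analyze mode:
#'   \code{spike_events}, \code{stimulus_events}, \code{layer_table}.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(mode = c("simulate+analyze", "simulate", "analyze"),
                       seed = 1L,
                       sim = list(),
                       detection = list(),
                       sorting = list(),
                       psth = list(),
                       aggregation = list(),
                       continuous_demo_s = 4,
                       group = "NI",
                       paths = list()) {
  mode <- match.arg(mode)
  merge_defaults <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    defaults[names(user)] <- user
    defaults
  }
  sim$seed <- NULL  # the master seed governs the simulator
  cfg <- list(
    mode = mode,
    seed = as.integer(seed),
    sim = do.call(sim_config, c(list(seed = as.integer(seed)), sim)),
    detection = merge_defaults(
      list(highpass_hz = 300, order = 2, k_rms = 4, dead_time_ms = 1,
           pre_ms = 0.6, post_ms = 1.2), detection),
    sorting = merge_defaults(
      list(max_k = 5, k1_threshold = 0.25, min_snippets = 10,
           restarts = 10, var_threshold = 0.10), sorting),
    psth = merge_defaults(
      list(t_pre_ms = 50, t_post_ms = 450,
           early = analysis_windows()$early,
           late = analysis_windows()$late,
           background = analysis_windows()$background), psth),
    aggregation = merge_defaults(list(c_sd = 3), aggregation),
    continuous_demo_s = continuous_demo_s,
    group = group,
    paths = paths)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' The configuration file uses nested key-value sections mirroring the
#' arguments of \code{\link{run_config}}; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a \code{run_config} (read) or \code{path} (write).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("mode", "seed", "sim", "detection", "sorting", "psth",
             "aggregation", "continuous_demo_s", "group", "paths")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in c("sim", "detection", "sorting", "psth", "aggregation",
               "paths"))
    if (!is.null(y[[nm]])) y[[nm]] <- as.list(y[[nm]])
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config a \code{run_config} to serialize.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- unclass(config)
  y$sim <- unclass(y$sim)
  y$sim$early_gain_by_layer <- as.list(y$sim$early_gain_by_layer)
  y$sim$late_gain_by_layer <- as.list(y$sim$late_gain_by_layer)
  y$sim$injury_effect_by_layer <- as.list(y$sim$injury_effect_by_layer)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full simulate/analyze pipeline
#'
#' Executes, in order: stimulus-schedule and spike-train simulation (or
#' event-table ingestion in analyze mode); synthesis of a short continuous
#' trace from the start of the first session, high-pass filtering,
#' RMS-threshold detection, and per-channel sorting (the trace stage, run
#' when \code{continuous_demo_s > 0}); PSTH construction per channel,
#' session, and nerve; channel exclusion; background subtraction; phase
#' averaging; peak/CoM extraction; nerve pooling; baseline normalization;
#' and layer-by-phase summaries. All tables are written as CSV together
#' with a provenance JSON sufficient to repeat the run. Deterministic for
#' a fixed seed.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the output file paths and the in-memory
#'   result tables.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  outputs <- list()
  simulate <- config$mode %in% c("simulate", "simulate+analyze")
  analyze <- config$mode %in% c("analyze", "simulate+analyze")

  if (simulate) {
    sim <- config$sim
    schedule <- generate_stimulus_schedule(sim)
    tr <- generate_spike_trains(sim, schedule)
    spikes <- tr$spikes
    layer_map <- data.frame(channel = seq_len(sim$n_channels),
                            layer = sim$layer_of_channel,
                            group = config$group)
    say("simulated %d stimuli, %d spikes on %d channels",
        nrow(schedule), nrow(spikes), sim$n_channels)
    outputs$stimulus_events <- file.path(out_dir, "stimulus_events.csv")
    write_events_csv(schedule, outputs$stimulus_events)
    outputs$spike_events <- file.path(out_dir, "spike_events.csv")
    write_events_csv(spikes, outputs$spike_events)
    outputs$layer_table <- file.path(out_dir, "layer_table.csv")
    write_events_csv(layer_map, outputs$layer_table)
    outputs$ground_truth <- file.path(out_dir, "ground_truth_units.csv")
    write_events_csv(tr$ground_truth$unit_map, outputs$ground_truth)

    if (config$continuous_demo_s > 0) {
      t0 <- min(schedule$time_s) - 0.1
      seg <- spikes[spikes$time_s >= t0 &
                      spikes$time_s <= t0 + config$continuous_demo_s - 0.005, ]
      rec <- generate_continuous(sim, seg,
                                 duration_s = config$continuous_demo_s,
                                 t_start_s = t0)
      outputs$recording <- file.path(out_dir, "recording")
      write_recording(rec, outputs$recording)
      det <- config$detection
      filt <- highpass_filter(rec, det$highpass_hz, det$order)
      ev <- detect_spikes(filt, k_rms = det$k_rms,
                          dead_time_ms = det$dead_time_ms,
                          pre_ms = det$pre_ms, post_ms = det$post_ms)
      say("trace stage: %d events detected in %.1f s of continuous data",
          nrow(ev$events), config$continuous_demo_s)
      outputs$detected_events <- file.path(out_dir, "detected_events.csv")
      write_events_csv(ev$events, outputs$detected_events)
      srt <- config$sorting
      reports <- list()
      assigns <- list()
      for (ch in sort(unique(ev$events$channel))) {
        idx <- which(ev$events$channel == ch)
        feats <- snippet_features(ev$snippets[idx, , drop = FALSE],
                                  rec$sampling_rate)
        ua <- sort_channel(feats, max_k = srt$max_k,
                           k1_threshold = srt$k1_threshold,
                           min_snippets = srt$min_snippets,
                           restarts = srt$restarts,
                           var_threshold = srt$var_threshold,
                           seed = config$seed + ch)
        reports[[length(reports) + 1L]] <- data.frame(
          channel = ch, n_snippets = ua$n_snippets, chosen_k = ua$chosen_k,
          best_silhouette = if (length(ua$silhouette_by_k))
            max(ua$silhouette_by_k, na.rm = TRUE) else NA_real_)
        assigns[[length(assigns) + 1L]] <- data.frame(
          event_id = idx, channel = ch, unit_label = ua$labels)
      }
      outputs$sorting_report <- file.path(out_dir, "sorting_report.csv")
      write_events_csv(do.call(rbind, reports), outputs$sorting_report)
      outputs$unit_assignments <- file.path(out_dir, "unit_assignments.csv")
      write_events_csv(do.call(rbind, assigns), outputs$unit_assignments)
    }
  } else {
    need <- c("spike_events", "stimulus_events", "layer_table")
    miss <- need[!vapply(need, function(nm)
      !is.null(config$paths[[nm]]) && file.exists(config$paths[[nm]]), TRUE)]
    if (length(miss))
      stop("analyze mode requires input path(s): ",
           paste(miss, collapse = ", "))
    spikes <- read_events_csv(config$paths$spike_events)
    schedule <- read_events_csv(config$paths$stimulus_events)
    layer_map <- read_events_csv(config$paths$layer_table)
  }

  results <- list()
  if (analyze) {
    channels <- sort(unique(layer_map$channel))
    raw <- session_psths(spikes, schedule, channels)
    excl <- exclude_unresponsive_channels(raw,
                                          c_sd = config$aggregation$c_sd,
                                          windows = list(config$psth$early,
                                                         config$psth$late),
                                          bg_window = config$psth$background)
    say("channel exclusion: %d retained, %d removed",
        length(excl$retained), length(excl$removed))
    raw <- raw[vapply(raw, function(p) p$channel %in% excl$retained, TRUE)]
    sub <- lapply(raw, subtract_background, window = config$psth$background)
    phase <- phase_average_psths(sub)
    meas <- psth_measurements(phase, windows = list(
      early = config$psth$early, late = config$psth$late))
    n_na_com <- sum(is.na(meas$com_ms))
    if (n_na_com > 0)
      say("%d zero-mass CoM value(s) propagated as missing", n_na_com)
    outputs$psth_measurements <- file.path(out_dir, "psth_measurements.csv")
    write_events_csv(meas, outputs$psth_measurements)

    pooled <- pool_nerves(meas)
    normed <- normalize_to_baseline(pooled, "amplitude",
                                    by = c("channel", "window"))
    normed <- merge(normed, layer_map[, c("channel", "layer")],
                    by = "channel", sort = TRUE)
    normed <- normed[order(normed$window, normed$channel, normed$phase), ]
    outputs$normalized_measurements <-
      file.path(out_dir, "normalized_measurements.csv")
    write_events_csv(normed, outputs$normalized_measurements)

    summ_amp <- group_summary(normed, "amplitude", c("window", "layer", "phase"))
    summ_pct <- group_summary(normed, "amplitude_pct",
                              c("window", "layer", "phase"))
    summ_com <- group_summary(normed, "com_ms", c("window", "layer", "phase"))
    summ_amp$measure <- "amplitude"
    summ_pct$measure <- "amplitude_pct_of_baseline"
    summ_com$measure <- "com_ms"
    summary_tab <- rbind(summ_amp, summ_pct, summ_com)
    summary_tab$group <- config$group
    outputs$layer_summary <- file.path(out_dir, "layer_phase_summary.csv")
    write_events_csv(summary_tab, outputs$layer_summary)
    results <- list(measurements = meas, normalized = normed,
                    summary = summary_tab, retained = excl$retained,
                    removed = excl$removed)
  }

  prov <- list(package = "laminaPSTH",
               package_version = as.character(
                 utils::packageVersion("laminaPSTH")),
               r_version = R.version.string,
               seed = config$seed,
               config = jsonlite::fromJSON(jsonlite::toJSON(
                 unclass_deep(config), auto_unbox = TRUE, digits = NA)))
  outputs$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, outputs$provenance, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  outputs$log <- file.path(out_dir, "log.txt")
  writeLines(log_lines, outputs$log)
  invisible(c(outputs, list(results = results)))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}
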