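#' Session-to-phase assignment
#'
#' Sessions run every 10 min; analysis groups them into 30-min phases of
#' \code{sessions_per_phase} sessions: all pre-intervention sessions form
#' phase 0 (baseline), post-intervention sessions form phases 1, 2, ...
#'
#' @param sessions_pre,sessions_post session counts before/after the
#'   intervention.
#' @param sessions_per_phase sessions per phase (default 3).
#' @return data.frame with columns \code{session}, \code{phase},
#'   \code{pre}.
#' @export
phase_schedule <- function(sessions_pre, sessions_post,
                           sessions_per_phase = 3L) {
  stopifnot(sessions_pre >= 0, sessions_post >= 0, sessions_per_phase >= 1)
  n <- sessions_pre + sessions_post
  phase <- c(rep(0L, sessions_pre),
             as.integer(ceiling(seq_len(sessions_post) / sessions_per_phase)))
  data.frame(session = seq_len(n), phase = phase, pre = phase == 0L)
}

#' Per-channel, per-session, per-nerve PSTHs from an event stream
#'
#' Builds one raw PSTH for every combination of channel, session, and
#' stimulated nerve present in the schedule.
#'
#' @param spikes data.frame with \code{time_s} and \code{channel} (all
#'   threshold crossings of a channel; unit identity is not used).
#' @param schedule stimulus schedule (\code{time_s}, \code{nerve},
#'   \code{session}, \code{phase}).
#' @param channels channel ids to analyze; defaults to all in
#'   \code{spikes}.
#' @return list of raw \code{psth} objects with channel/session/nerve/phase
#'   identifiers set.
#' @export
session_psths <- function(spikes, schedule, channels = NULL) {
  if (is.null(channels)) channels <- sort(unique(spikes$channel))
  keys <- unique(schedule[, c("session", "nerve", "phase")])
  out <- list()
  sp_ch <- split(spikes$time_s, spikes$channel)
  for (ch in channels) {
    times <- sp_ch[[as.character(ch)]]
    if (is.null(times)) times <- numeric(0)
    for (r in seq_len(nrow(keys))) {
      stim <- schedule$time_s[schedule$session == keys$session[r] &
                                schedule$nerve == keys$nerve[r]]
      out[[length(out) + 1L]] <- build_psth(
        times, stim, channel = ch, nerve = keys$nerve[r],
        session = keys$session[r], phase = keys$phase[r])
    }
  }
  out
}

#' Average session PSTHs into phase PSTHs
#'
#' Averages, per channel and nerve, the PSTHs of all sessions belonging to
#' the same phase.
#'
#' @param psths list of \code{psth} objects carrying channel, nerve,
#'   session, and phase identifiers.
#' @return list of phase-level \code{psth} objects.
#' @export
phase_average_psths <- function(psths) {
  key <- vapply(psths, function(p)
    paste(p$channel, p$nerve, p$phase, sep = "\r"), "")
  lapply(split(psths, key), average_psths)
}

#' Extract peak amplitude and CoM latency measurements
#'
#' For each PSTH and each analysis window, extracts the peak amplitude
#' (max spikes/bin) and the center-of-mass latency into a tidy table.
#'
#' @param psths list of \code{psth} objects.
#' @param windows named list of windows (default early + late from
#'   \code{\link{analysis_windows}}).
#' @return data.frame: \code{channel}, \code{session}, \code{phase},
#'   \code{nerve}, \code{window}, \code{amplitude}, \code{com_ms},
#'   \code{n_stimuli}. A zero-mass CoM propagates as \code{NA}.
#' @export
psth_measurements <- function(psths,
                              windows = analysis_windows()[c("early", "late")]) {
  rows <- lapply(psths, function(p) {
    do.call(rbind, lapply(names(windows), function(wn) {
      data.frame(channel = p$channel,
                 session = if (is.na(p$session)) NA_integer_
                           else as.integer(p$session),
                 phase = if (is.na(p$phase)) NA_integer_
                         else as.integer(p$phase),
                 nerve = as.character(p$nerve),
                 window = wn,
                 amplitude = peak_amplitude(p, windows[[wn]]),
                 com_ms = center_of_mass(p, windows[[wn]]),
                 n_stimuli = p$n_stimuli)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove channels that never responded to stimulation
#'
#' A channel is retained if, in at least one session (either nerve), its
#' raw early- or late-window peak exceeds the pre-stimulus background mean
#' by more than \code{c_sd} background standard deviations. Channels that
#' fail this in every session of the experiment are excluded.
#'
#' @param psths list of raw (not background-subtracted) session
#'   \code{psth} objects from \code{\link{session_psths}}.
#' @param c_sd responsiveness criterion in background SDs (default 3).
#' @param windows response windows tested (default early and late).
#' @param bg_window background window.
#' @return list with \code{retained} and \code{removed} channel ids and a
#'   per-channel logical \code{responsive} table.
#' @export
exclude_unresponsive_channels <- function(psths, c_sd = 3,
                                          windows = analysis_windows()[c("early", "late")],
                                          bg_window = analysis_windows()$background) {
  stopifnot(length(psths) > 0)
  if (any(vapply(psths, `[[`, TRUE, "background_subtracted")))
    stop("responsiveness must be judged on raw PSTHs")
  resp <- vapply(psths, function(p) {
    idx <- psth_window_index(p, bg_window)
    thr <- mean(p$counts[idx]) + c_sd * stats::sd(p$counts[idx])
    any(vapply(windows, function(w) peak_amplitude(p, w) > thr, TRUE))
  }, TRUE)
  ch <- vapply(psths, function(p) as.integer(p$channel), 1L)
  responsive <- tapply(resp, ch, any)
  retained <- as.integer(names(responsive))[responsive]
  removed <- as.integer(names(responsive))[!responsive]
  if (length(retained) == 0) stop("no responsive channels retained")
  list(retained = retained, removed = removed,
       responsive = data.frame(channel = as.integer(names(responsive)),
                               responsive = as.logical(responsive)))
}

#' Pool measurements across the two stimulated nerves
#'
#' Averages the ulnar- and median-nerve measurements per channel, phase (or
#' session), and window. Rows with only one nerve available are carried
#' through with \code{n_nerves = 1}.
#'
#' @param measurements tidy table from \code{\link{psth_measurements}}.
#' @param value_cols numeric columns to average.
#' @return data.frame keyed by channel/session/phase/window with pooled
#'   values and an \code{n_nerves} column.
#' @export
pool_nerves <- function(measurements,
                        value_cols = c("amplitude", "com_ms")) {
  keys <- intersect(c("channel", "session", "phase", "window"),
                    names(measurements))
  keys <- keys[vapply(keys, function(k) !all(is.na(measurements[[k]])),
                      TRUE)]
  kf <- interaction(lapply(measurements[keys], factor, exclude = NULL),
                    drop = TRUE, lex.order = TRUE)
  parts <- lapply(split(measurements, kf), function(g) {
    out <- g[1, keys, drop = FALSE]
    for (v in value_cols)
      out[[v]] <- mean(g[[v]][!is.na(g[[v]])])
    out$n_nerves <- length(unique(g$nerve))
    out
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Normalize phase measurements to the pre-intervention baseline
#'
#' Expresses each value as a percentage of the same channel's (and
#' window's) phase-0 baseline: \code{100 * value / baseline}. Rows whose
#' baseline is missing or not positive get \code{NA} and are counted in
#' the \code{n_unnormalized} attribute.
#'
#' @param measurements table with a \code{phase} column (0 = baseline).
#' @param value_col column to normalize (default \code{"amplitude"}).
#' @param by grouping columns identifying a baseline (default channel and
#'   window).
#' @return the input with an added \code{<value_col>_pct} column.
#' @export
normalize_to_baseline <- function(measurements, value_col = "amplitude",
                                  by = c("channel", "window")) {
  by <- intersect(by, names(measurements))
  kf <- interaction(measurements[by], drop = TRUE, lex.order = TRUE)
  pct <- rep(NA_real_, nrow(measurements))
  n_missing <- 0L
  for (lev in levels(kf)) {
    idx <- which(kf == lev)
    base <- measurements[[value_col]][idx][measurements$phase[idx] == 0]
    base <- mean(base[!is.na(base)])
    if (!is.finite(base) || base <= 0) {
      n_missing <- n_missing + length(idx)
      next
    }
    pct[idx] <- 100 * measurements[[value_col]][idx] / base
  }
  measurements[[paste0(value_col, "_pct")]] <- pct
  attr(measurements, "n_unnormalized") <- n_missing
  measurements
}

#' Cell means and standard errors over grouping keys
#'
#' Summarizes a measurement column by mean, standard error of the mean
#' (sd / sqrt(n); 0 for a single value), and n over the requested keys,
#' e.g. group x layer x phase. \code{NA} values are dropped and counted;
#' empty cells are omitted.
#'
#' @param measurements tidy measurement table.
#' @param value_col column to summarize.
#' @param keys character vector of grouping columns.
#' @return data.frame with the keys plus \code{mean}, \code{sem},
#'   \code{n}.
#' @export
group_summary <- function(measurements, value_col = "amplitude",
                          keys = c("layer", "phase")) {
  keys <- intersect(keys, names(measurements))
  stopifnot(length(keys) > 0)
  kf <- interaction(measurements[keys], drop = TRUE, lex.order = TRUE)
  parts <- lapply(split(measurements, kf), function(g) {
    v <- g[[value_col]]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    out <- g[1, keys, drop = FALSE]
    out$mean <- mean(v)
    out$sem <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    out$n <- length(v)
    out
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Retained-channel counts per layer and group
#'
#' Bookkeeping table of how many retained channels fall in each cortical
#' layer for each experimental group.
#'
#' @param layer_map data.frame with \code{channel}, \code{layer}, and
#'   optionally \code{group} and \code{animal}.
#' @param retained channel ids retained after exclusion; default all.
#' @return data.frame of counts per layer (x group if present).
#' @export
layer_channel_counts <- function(layer_map, retained = layer_map$channel) {
  m <- layer_map[layer_map$channel %in% retained, , drop = FALSE]
  keys <- intersect(c("layer", "group"), names(m))
  agg <- stats::aggregate(m$channel, by = m[keys], FUN = length)
  names(agg)[ncol(agg)] <- "channels"
  agg[order(match(agg$layer, cortical_layers())), , drop = FALSE]
}

#' Two-sided permutation test for a difference in means
#'
#' Permutes group labels \code{n_perm} times and reports the add-one
#' estimator \code{p = (1 + #(|diff_perm| >= |diff_obs|)) / (1 + n_perm)},
#' which is never 0 and super-uniform under the null. A descriptive
#' companion to the summaries; no repeated-measures structure is modeled.
#'
#' @param a,b numeric vectors (the two cells).
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed.
#' @return p-value in (0, 1].
#' @export
permutation_group_test <- function(a, b, n_perm = 999, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (length(a) == 0 || length(b) == 0) stop("both cells must be non-empty")
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  with_local_seed(seed, {
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pooled), na)
      d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
      if (d >= obs) exceed <- exceed + 1L
    }
    (1 + exceed) / (1 + n_perm)
  })
}
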