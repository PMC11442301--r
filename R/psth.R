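#' Default analysis windows
#'
#' The early (A-beta) and late (A-delta) response windows, 10-19 ms and
#' 21-35 ms after the stimulus, and the pre-stimulus background window,
#' -50 to -5 ms. Windows address inclusive bin labels.
#'
#' @return named list of length-2 integer vectors \code{c(t1, t2)}.
#' @export
analysis_windows <- function() {
  list(early = c(10L, 19L), late = c(21L, 35L), background = c(-50L, -5L))
}

new_psth <- function(counts, bins, n_stimuli, channel = NA, nerve = NA,
                     session = NA, phase = NA,
                     background_subtracted = FALSE, background_level = 0) {
  structure(list(counts = counts, bins = bins, n_stimuli = n_stimuli,
                 channel = channel, nerve = nerve, session = session,
                 phase = phase,
                 background_subtracted = background_subtracted,
                 background_level = background_level, bin_ms = 1),
            class = "psth")
}

#' Build a peristimulus time histogram
#'
#' Spike times relative to each stimulus are collected from 50 ms before
#' to 450 ms after the stimulus and counted in 1 ms bins, summed across
#' stimuli. Bins are centred on integer millisecond labels: bin \eqn{b}
#' covers \eqn{[b - 0.5, b + 0.5)} ms, giving 500 bins labelled -50..449.
#' A spike at exactly -50.0 ms is included; one at +450.0 ms is not.
#'
#' @param spike_times_s spike times (s).
#' @param stim_times_s stimulus times (s), same clock; must be non-empty.
#' @param t_pre_ms,t_post_ms peri-stimulus span (default 50 before, 450
#'   after).
#' @param channel,nerve,session,phase optional identifiers carried on the
#'   object.
#' @return object of class \code{"psth"} with integer \code{counts} and
#'   bin labels \code{bins}.
#' @export
build_psth <- function(spike_times_s, stim_times_s, t_pre_ms = 50,
                       t_post_ms = 450, channel = NA, nerve = NA,
                       session = NA, phase = NA) {
  if (length(stim_times_s) == 0) stop("no stimuli supplied")
  bins <- seq.int(-t_pre_ms, t_post_ms - 1L)
  nb <- length(bins)
  counts <- integer(nb)
  st <- sort(spike_times_s)
  lo_s <- (-t_pre_ms - 0.5) / 1000
  hi_s <- (t_post_ms - 0.5) / 1000
  for (s in stim_times_s) {
    i0 <- findInterval(s + lo_s, st) + 1L
    i1 <- findInterval(s + hi_s, st)
    if (i1 < i0) next
    rel_ms <- (st[i0:i1] - s) * 1000
    lab <- floor(rel_ms + 0.5)
    lab <- lab[lab >= -t_pre_ms & lab <= t_post_ms - 1]
    counts <- counts + tabulate(lab + t_pre_ms + 1L, nb)
  }
  new_psth(counts, bins, n_stimuli = length(stim_times_s),
           channel = channel, nerve = nerve, session = session,
           phase = phase)
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("psth: %d bins (%d..%d ms), %s stimuli%s\n",
              length(x$bins), min(x$bins), max(x$bins),
              format(x$n_stimuli),
              if (x$background_subtracted) ", background-subtracted" else ""))
  invisible(x)
}

psth_window_index <- function(psth, window) {
  if (window[1] >= window[2]) stop("window must satisfy t1 < t2")
  if (window[1] < min(psth$bins) || window[2] > max(psth$bins))
    stop("analysis window outside PSTH span")
  which(psth$bins >= window[1] & psth$bins <= window[2])
}

#' Subtract pre-stimulus background activity
#'
#' Subtracts the mean per-bin count over the background window (default
#' -50 to -5 ms before the stimulus) from every bin, compensating for
#' differences in detection thresholding across channels. Counts may
#' become negative. Subtracting twice is an error.
#'
#' @param psth a \code{psth}.
#' @param window background window as inclusive bin labels.
#' @return the background-subtracted \code{psth}
#'   (\code{background_subtracted = TRUE}, with the subtracted level in
#'   \code{background_level}).
#' @export
subtract_background <- function(psth, window = analysis_windows()$background) {
  stopifnot(inherits(psth, "psth"))
  if (psth$background_subtracted)
    stop("background already subtracted")
  idx <- psth_window_index(psth, window)
  bg <- mean(psth$counts[idx])
  psth$counts <- psth$counts - bg
  psth$background_subtracted <- TRUE
  psth$background_level <- bg
  psth
}

#' Peak amplitude within an analysis window
#'
#' The maximum per-bin spike count over the inclusive bin labels
#' \code{window[1]..window[2]} (spikes/bin).
#'
#' @param psth a \code{psth}.
#' @param window length-2 vector of inclusive bin labels.
#' @return numeric scalar.
#' @export
peak_amplitude <- function(psth, window = analysis_windows()$early) {
  stopifnot(inherits(psth, "psth"))
  max(psth$counts[psth_window_index(psth, window)])
}

#' Center-of-mass latency within an analysis window
#'
#' The spike-count-weighted mean bin time over the window,
#' \eqn{CoM = \sum_{t1}^{t2} (spikes \times t) / \sum_{t1}^{t2} spikes}.
#' On background-subtracted histograms negative bins are clipped to zero
#' by default so the weights remain a valid mass. If the window holds no
#' spike mass the latency is undefined and \code{NA} is returned.
#'
#' @param psth a \code{psth}.
#' @param window length-2 vector of inclusive bin labels.
#' @param clip_negative clip negative (background-subtracted) counts to 0.
#' @return latency in ms, or \code{NA_real_} for zero mass.
#' @export
center_of_mass <- function(psth, window = analysis_windows()$early,
                           clip_negative = TRUE) {
  stopifnot(inherits(psth, "psth"))
  idx <- psth_window_index(psth, window)
  w <- psth$counts[idx]
  if (clip_negative) w[w < 0] <- 0
  tot <- sum(w)
  if (tot <= 0) return(NA_real_)
  sum(w * psth$bins[idx]) / tot
}

#' Conduction velocity from response latency
#'
#' \code{distance / (latency - offset)}, where \code{offset} is the
#' non-conduction (synaptic/central) delay. A 15 ms cortical latency over
#' a 0.9 m nerve path corresponds to 60 m/s, in the A-beta range.
#'
#' @param latency_ms response latency (ms).
#' @param distance_m conduction path length (m), > 0.
#' @param offset_ms non-conduction delay (ms); must be < latency.
#' @return velocity in m/s.
#' @export
conduction_velocity <- function(latency_ms, distance_m, offset_ms = 0) {
  if (any(distance_m <= 0)) stop("distance must be > 0")
  if (any(latency_ms <= offset_ms)) stop("latency must exceed offset")
  distance_m / ((latency_ms - offset_ms) / 1000)
}

#' Average PSTHs bin by bin
#'
#' Arithmetic per-bin mean of PSTHs with identical binning and matching
#' background-subtraction state, e.g. the three session histograms of one
#' 30-min phase. \code{n_stimuli} is recorded as the mean across inputs.
#'
#' @param psths list of \code{psth} objects.
#' @return a \code{psth} with (generally non-integer) mean counts. Any
#'   identifier (channel, nerve, session, phase) shared by all inputs is
#'   kept, otherwise set to \code{NA}.
#' @export
average_psths <- function(psths) {
  stopifnot(length(psths) >= 1, all(vapply(psths, inherits, TRUE, "psth")))
  b0 <- psths[[1]]$bins
  for (p in psths) {
    if (!identical(p$bins, b0)) stop("PSTHs have mismatched bins")
    if (!identical(p$background_subtracted,
                   psths[[1]]$background_subtracted))
      stop("PSTHs mix background-subtracted and raw counts")
  }
  shared <- function(field) {
    v <- unique(vapply(psths, function(p) as.character(p[[field]])[1], ""))
    if (length(v) == 1) psths[[1]][[field]] else NA
  }
  new_psth(rowMeans(vapply(psths, `[[`, numeric(length(b0)), "counts")),
           bins = b0,
           n_stimuli = mean(vapply(psths, `[[`, numeric(1), "n_stimuli")),
           channel = shared("channel"), nerve = shared("nerve"),
           session = shared("session"), phase = shared("phase"),
           background_subtracted = psths[[1]]$background_subtracted,
           background_level = mean(vapply(psths, `[[`, numeric(1),
                                          "background_level")))
}
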