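# Independent oracles and fixture builders used across the suite.

# Brute-force weighted-mean latency over a window of a PSTH, written
# directly from the defining sum (independent of center_of_mass()).
brute_force_com <- function(counts, bins, t1, t2, clip = TRUE) {
  sel <- bins >= t1 & bins <= t2
  w <- counts[sel]
  if (clip) w[w < 0] <- 0
  if (sum(w) <= 0) return(NA_real_)
  num <- 0
  den <- 0
  for (i in seq_along(w)) {
    num <- num + w[i] * bins[sel][i]
    den <- den + w[i]
  }
  num / den
}

# Brute-force mean silhouette from the pairwise-distance definition,
# with explicit loops (independent of mean_silhouette()).
brute_force_silhouette <- function(points, labels) {
  if (is.vector(points)) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      dmat[i, j] <- sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(dmat[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(dmat[i, labels == cl]))
    }
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(s)
}

# Greedy one-to-one matching of detected to true event times within a
# tolerance; returns hits for recall/precision.
match_events <- function(true_s, detected_s, tol_s = 5e-4) {
  truth <- sort(true_s)
  det <- sort(detected_s)
  used <- rep(FALSE, length(det))
  hits <- 0L
  for (x in truth) {
    j <- which(!used & abs(det - x) <= tol_s)
    if (length(j)) {
      used[j[which.min(abs(det[j] - x))]] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}

# Snippets from k planted units on one channel: distinct biphasic
# templates plus white noise, aligned as detection would align them.
planted_unit_snippets <- function(k, n_per = 60, noise_sd = 5,
                                  sampling_rate = 25000) {
  amps <- c(60, 105, 160, 220, 290, 370)[seq_len(k)]
  pfrac <- rep_len(c(0.3, 0.45, 0.6), k)
  nsd <- rep_len(c(0.08, 0.12, 0.16), k)
  psd <- rep_len(c(0.18, 0.26, 0.34), k)
  pdel <- rep_len(c(0.35, 0.5, 0.65), k)
  snips <- list()
  for (u in seq_len(k)) {
    tpl <- waveform_template(sampling_rate, neg_amp = amps[u],
                             pos_amp = pfrac[u] * amps[u],
                             neg_sd_ms = nsd[u], pos_sd_ms = psd[u],
                             pos_delay_ms = pdel[u], span_ms = c(0.6, 1.2))
    snips[[u]] <- matrix(rep(tpl, n_per), nrow = n_per, byrow = TRUE) +
      matrix(stats::rnorm(n_per * length(tpl), 0, noise_sd), nrow = n_per)
  }
  list(snippets = do.call(rbind, snips),
       labels = rep(seq_len(k), each = n_per))
}

# A psth object with given counts, for direct unit tests.
make_psth <- function(counts, t_pre_ms = 50, n_stimuli = 100, ...) {
  p <- build_psth(numeric(0), 0, t_pre_ms = t_pre_ms,
                  t_post_ms = length(counts) - t_pre_ms, ...)
  p$counts <- counts
  p$n_stimuli <- n_stimuli
  p
}
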