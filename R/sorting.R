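#' Scalar waveform descriptors of a spike snippet
#'
#' Computes the seven features used for per-channel unit separation:
#' number of zero crossings; width (FWHM, ms) of the most prominent peak
#' (the extremum of largest absolute amplitude); amplitude and latency of
#' the positive and the negative extremum; and whether the negative
#' polarity occurred first. Latencies are measured from the start of the
#' snippet and refined by parabolic sub-sample interpolation around the
#' extremum (standard practice; without it, sample-quantized latencies
#' collapse into discrete atoms that destabilize downstream clustering).
#' Zero samples count as their own sign level, so a deflection that
#' leaves and returns to exactly zero contributes two crossings.
#'
#' @param snippet numeric vector (uV), at least 8 samples, non-constant.
#' @param sampling_rate Hz.
#' @return named numeric vector with elements \code{n_zero_crossings},
#'   \code{peak_width_ms}, \code{pos_amp}, \code{neg_amp},
#'   \code{pos_latency_ms}, \code{neg_latency_ms}, \code{neg_first}.
#' @export
compute_features <- function(snippet, sampling_rate) {
  if (length(snippet) < 8) stop("snippet too short (need >= 8 samples)")
  if (max(snippet) == min(snippet)) stop("degenerate snippet: constant")
  dt_ms <- 1000 / sampling_rate
  t_ms <- (seq_along(snippet) - 1) * dt_ms

  sgn <- sign(snippet)
  zc <- sum(sgn[-1] != sgn[-length(sgn)])

  i_pos <- which.max(snippet)
  i_neg <- which.min(snippet)
  pos <- interpolate_peak(snippet, i_pos, dt_ms)
  neg <- interpolate_peak(snippet, i_neg, dt_ms)
  pos_amp <- pos$amp
  neg_amp <- neg$amp

  # most prominent peak: the extremum of largest |amplitude|
  if (abs(neg_amp) >= abs(pos_amp)) {
    i_pk <- i_neg
    y <- -snippet
  } else {
    i_pk <- i_pos
    y <- snippet
  }
  width <- fwhm_ms(y, i_pk, dt_ms)

  c(n_zero_crossings = zc,
    peak_width_ms = width,
    pos_amp = pos_amp,
    neg_amp = neg_amp,
    pos_latency_ms = pos$latency,
    neg_latency_ms = neg$latency,
    neg_first = as.numeric(neg$latency < pos$latency))
}

# Parabolic sub-sample refinement of an extremum: fits a parabola through
# the extremum and its two neighbours. At a snippet edge, or when the
# vertex is degenerate, the sample values are returned unchanged.
interpolate_peak <- function(x, i, dt_ms) {
  n <- length(x)
  if (i == 1 || i == n)
    return(list(amp = x[i], latency = (i - 1) * dt_ms))
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (denom == 0)
    return(list(amp = x[i], latency = (i - 1) * dt_ms))
  delta <- 0.5 * (x[i - 1] - x[i + 1]) / denom
  delta <- max(min(delta, 0.5), -0.5)
  amp <- x[i] - 0.25 * (x[i - 1] - x[i + 1]) * delta
  list(amp = amp, latency = (i - 1 + delta) * dt_ms)
}

# Full width at half maximum of the peak at index i_pk of y (peak positive
# in y). Crossing positions are linearly interpolated; if the trace never
# drops below half height before the snippet edge, the edge is used.
fwhm_ms <- function(y, i_pk, dt_ms) {
  half <- y[i_pk] / 2
  n <- length(y)
  left <- 1
  if (i_pk > 1) {
    for (i in seq(i_pk, 2, by = -1)) {
      if (y[i - 1] < half) {
        left <- (i - 1) + (half - y[i - 1]) / (y[i] - y[i - 1])
        break
      }
    }
  } else left <- i_pk
  right <- n
  if (i_pk < n) {
    for (i in seq(i_pk, n - 1)) {
      if (y[i + 1] < half) {
        right <- i + (y[i] - half) / (y[i] - y[i + 1])
        break
      }
    }
  } else right <- i_pk
  max(right - left, 0.5) * dt_ms  # floor of half a sample for spikes at an edge
}

#' Feature matrix for a set of snippets
#'
#' @param snippets matrix, one snippet per row.
#' @param sampling_rate Hz.
#' @return data.frame with one row per snippet and the seven columns of
#'   \code{\link{compute_features}}.
#' @export
snippet_features <- function(snippets, sampling_rate) {
  stopifnot(is.matrix(snippets))
  as.data.frame(t(apply(snippets, 1, compute_features,
                        sampling_rate = sampling_rate)))
}

#' PCA with a 10\%-variance component-retention rule
#'
#' Standardizes the feature columns (constant columns are dropped), runs a
#' principal component analysis, and keeps the components whose explained
#' variance ratio exceeds \code{var_threshold}. At least one component is
#' always retained.
#'
#' @param x numeric matrix or data.frame of features (rows = snippets).
#' @param var_threshold explained-variance ratio above which a component
#'   is kept (default 0.10).
#' @return list with \code{scores} (retained projections),
#'   \code{variance_ratios} (all components), \code{kept} (indices of
#'   retained components), and \code{dropped_features}.
#' @export
select_components <- function(x, var_threshold = 0.10) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 snippets")
  sds <- apply(x, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  xs <- scale(x[, !const, drop = FALSE])
  if (ncol(xs) == 0) stop("all features constant")
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  kept <- which(ratios > var_threshold)
  if (length(kept) == 0) kept <- 1L
  list(scores = pc$x[, kept, drop = FALSE],
       variance_ratios = ratios,
       kept = kept,
       dropped_features = colnames(x)[const])
}

#' Mean silhouette coefficient
#'
#' Standard silhouette with Euclidean distances:
#' \eqn{s(i) = (b_i - a_i) / \max(a_i, b_i)}, where \eqn{a_i} is the mean
#' distance of point \eqn{i} to the other members of its cluster and
#' \eqn{b_i} the smallest mean distance to any other cluster. Points in
#' singleton clusters, and points for which \eqn{a_i = b_i = 0} (all
#' distances degenerate), score 0.
#'
#' @param points numeric matrix (rows = points) or vector.
#' @param labels cluster labels, at least two distinct values.
#' @return mean of \eqn{s(i)} over all points.
#' @export
mean_silhouette <- function(points, labels) {
  if (is.vector(points)) points <- matrix(points, ncol = 1)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette is undefined for a single cluster")
  if (length(labels) != nrow(points))
    stop("labels and points disagree in length")
  d <- as.matrix(stats::dist(points))
  sizes <- tabulate(labels, k)
  # mean distance from each point to each cluster (sum / size)
  sums <- vapply(seq_len(k), function(cl)
    rowSums(d[, labels == cl, drop = FALSE]), numeric(nrow(points)))
  s <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    cl <- labels[i]
    if (sizes[cl] == 1) { s[i] <- 0; next }
    a <- sums[i, cl] / (sizes[cl] - 1)
    b <- min(sums[i, -cl] / sizes[-cl])
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(s)
}

#' Sort the spikes of one channel into units
#'
#' The per-channel sorter: waveform features are standardized and reduced
#' by \code{\link{select_components}} (components explaining more than 10\%
#' of the variance are kept), then k-means is run for k = 2..\code{max_k}
#' (k-means++ style multi-restart via \code{nstart}) and the cluster count
#' with the highest mean silhouette wins; ties go to the smaller k. If the
#' best silhouette falls below \code{k1_threshold} the channel is treated
#' as a single unit, as is any channel with fewer than \code{min_snippets}
#' spikes.
#'
#' @param features matrix or data.frame of waveform features (rows =
#'   snippets), e.g. from \code{\link{snippet_features}}.
#' @param max_k maximum number of clusters considered (default 5).
#' @param k1_threshold mean-silhouette level below which a single unit is
#'   assumed (default 0.25).
#' @param min_snippets below this many snippets everything is assigned to
#'   one unit (default 10).
#' @param restarts k-means restarts per k (default 10).
#' @param var_threshold passed to \code{\link{select_components}}.
#' @param seed seed making the sort reproducible (default 1).
#' @return object of class \code{"unit_assignment"}: list with
#'   \code{labels}, \code{chosen_k}, \code{silhouette_by_k},
#'   \code{variance_ratios}, \code{n_snippets}.
#' @export
sort_channel <- function(features, max_k = 5, k1_threshold = 0.25,
                         min_snippets = 10, restarts = 10,
                         var_threshold = 0.10, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n == 0) stop("empty feature set")
  one_unit <- function(sil = numeric(0), ratios = numeric(0))
    structure(list(labels = rep(1L, n), chosen_k = 1L,
                   silhouette_by_k = sil, variance_ratios = ratios,
                   n_snippets = n),
              class = "unit_assignment")
  if (n < min_snippets) return(one_unit())
  sel <- select_components(features, var_threshold)
  scores <- sel$scores
  n_distinct <- nrow(unique(scores))
  ks <- seq(2, min(max_k, n_distinct))
  if (length(ks) == 0 || ks[1] > min(max_k, n_distinct))
    return(one_unit(ratios = sel$variance_ratios))
  with_local_seed(seed, {
    sil <- stats::setNames(rep(NA_real_, length(ks)), ks)
    fits <- vector("list", length(ks))
    for (j in seq_along(ks)) {
      km <- tryCatch(
        stats::kmeans(scores, centers = ks[j], nstart = restarts,
                      iter.max = 100),
        error = function(e) NULL)
      if (is.null(km)) next
      fits[[j]] <- km
      sil[j] <- mean_silhouette(scores, km$cluster)
    }
    if (all(is.na(sil))) return(one_unit(sil, sel$variance_ratios))
    best <- which.max(sil)  # ties resolve to the smallest k
    if (sil[best] < k1_threshold)
      return(one_unit(sil, sel$variance_ratios))
    structure(list(labels = fits[[best]]$cluster,
                   chosen_k = ks[best],
                   silhouette_by_k = sil,
                   variance_ratios = sel$variance_ratios,
                   n_snippets = n),
              class = "unit_assignment")
  })
}

#' @export
print.unit_assignment <- function(x, ...) {
  cat(sprintf("unit_assignment: %d snippets -> %d unit(s)\n",
              x$n_snippets, x$chosen_k))
  if (length(x$silhouette_by_k))
    cat("  mean silhouette by k:",
        paste(sprintf("k=%s: %.3f", names(x$silhouette_by_k),
                      x$silhouette_by_k), collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones. Used to score sorting recovery against planted units.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (nij - expected) / denom
}
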