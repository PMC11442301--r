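test_that("features of an analytic biphasic snippet are exact", {
  fs <- 10000  # 0.1 ms per sample
  s <- numeric(12)
  s[4] <- -80  # 0.3 ms after snippet start
  s[8] <- 40   # 0.7 ms
  f <- compute_features(s, fs)
  expect_equal(unname(f["neg_amp"]), -80)
  expect_equal(unname(f["pos_amp"]), 40)
  expect_equal(unname(f["neg_latency_ms"]), 0.3)
  expect_equal(unname(f["pos_latency_ms"]), 0.7)
  expect_equal(unname(f["neg_first"]), 1)
})

test_that("sign-flipping a snippet swaps the polarity features", {
  fs <- 25000
  tpl <- waveform_template(fs, neg_amp = 90, pos_amp = 40)
  f <- compute_features(as.numeric(tpl), fs)
  g <- compute_features(-as.numeric(tpl), fs)
  expect_equal(unname(g["pos_amp"]), -unname(f["neg_amp"]))
  expect_equal(unname(g["neg_amp"]), -unname(f["pos_amp"]))
  expect_equal(unname(g["pos_latency_ms"]), unname(f["neg_latency_ms"]))
  expect_equal(unname(g["neg_latency_ms"]), unname(f["pos_latency_ms"]))
  expect_equal(unname(g["neg_first"]), 1 - unname(f["neg_first"]))
  expect_equal(unname(g["peak_width_ms"]), unname(f["peak_width_ms"]))
})

test_that("half-sine lobe: two zero crossings and the analytic FWHM", {
  fs <- 1e6  # fine sampling so interpolation error is negligible
  T_ms <- 1
  n <- round(T_ms / 1000 * fs)
  t <- seq(0, T_ms, length.out = n + 1)
  s <- sinpi(t / T_ms)  # exact zeros at both endpoints
  f <- compute_features(s, fs)
  expect_equal(unname(f["n_zero_crossings"]), 2)
  # sin(pi t/T) >= 1/2 on [T/6, 5T/6] -> FWHM = 2T/3
  expect_equal(unname(f["peak_width_ms"]), 2 * T_ms / 3, tolerance = 1e-4)
})

test_that("feature extraction is translation-equivariant in time", {
  fs <- 25000
  tpl <- as.numeric(waveform_template(fs, neg_amp = 70, pos_amp = 30))
  shifted <- c(numeric(5), tpl)
  f0 <- compute_features(c(tpl, numeric(5)), fs)
  f1 <- compute_features(shifted, fs)
  dt <- 5 * 1000 / fs
  expect_equal(unname(f1["neg_latency_ms"] - f0["neg_latency_ms"]), dt)
  expect_equal(unname(f1["pos_latency_ms"] - f0["pos_latency_ms"]), dt)
  for (nm in c("peak_width_ms", "pos_amp", "neg_amp", "neg_first"))
    expect_equal(unname(f1[nm]), unname(f0[nm]), tolerance = 1e-9)
})

test_that("degenerate snippets are rejected", {
  expect_error(compute_features(rep(1, 20), 25000), "constant")
  expect_error(compute_features(c(1, -1), 25000), "too short")
})

test_that("component selection follows the 10% explained-variance rule", {
  set.seed(8)
  # variance concentrated on one feature; the rest constant
  x1 <- cbind(rnorm(500), 1, 2, 3)
  s1 <- select_components(x1)
  expect_equal(ncol(s1$scores), 1)
  expect_equal(s1$variance_ratios[1], 1, tolerance = 1e-12)
  # isotropic standardized 7-D Gaussian: each ratio near 1/7, all kept
  x2 <- matrix(rnorm(10000 * 7), ncol = 7)
  s2 <- select_components(x2)
  expect_equal(length(s2$variance_ratios), 7)
  expect_true(all(abs(s2$variance_ratios - 1 / 7) < 0.02))
  expect_equal(ncol(s2$scores), 7)
  expect_equal(sum(s2$variance_ratios), 1, tolerance = 1e-9)
  expect_error(select_components(x2[1, , drop = FALSE]), "at least 2")
})

test_that("mean silhouette matches hand-computable geometries", {
  # two tight, far-separated pairs
  pts <- rbind(c(0, 0), c(0, 0.01), c(100, 0), c(100, 0.01))
  expect_gt(mean_silhouette(pts, c(1, 1, 2, 2)), 0.95)
  # all points coincident: a = b = 0 -> s = 0
  z <- matrix(0, nrow = 6, ncol = 2)
  expect_equal(mean_silhouette(z, rep(1:2, 3)), 0)
  expect_error(mean_silhouette(pts, rep(1, 4)), "single cluster")
})

test_that("mean silhouette matches the brute-force pairwise oracle", {
  set.seed(33)
  for (i in 1:5) {
    pts <- matrix(rnorm(50 * 2), ncol = 2)
    labs <- sample(1:3, 50, replace = TRUE)
    expect_equal(mean_silhouette(pts, labs),
                 brute_force_silhouette(pts, labs), tolerance = 1e-9)
  }
})

test_that("sorter recovers planted well-separated clusters", {
  set.seed(44)
  # centers in generic position: every feature varies across units
  centers <- rbind(c(0, 0, 0), c(4, 3, 2), c(-3, 4, -4))
  labs <- rep(1:3, each = 50)
  x <- centers[labs, ] + matrix(rnorm(150 * 3, 0, 0.1), ncol = 3)
  ua <- sort_channel(x, seed = 1)
  expect_equal(ua$chosen_k, 3)
  expect_gte(adjusted_rand_index(labs, ua$labels), 0.99)
})

test_that("sorter falls back to one unit for unstructured data", {
  set.seed(45)
  x <- matrix(rnorm(200 * 4), ncol = 4)
  ua <- sort_channel(x, seed = 1)
  expect_equal(ua$chosen_k, 1)
  expect_true(all(ua$labels == 1))
  expect_lt(max(ua$silhouette_by_k, na.rm = TRUE), 0.25)
})

test_that("cluster-count cap and the small-sample rule are respected", {
  set.seed(46)
  centers <- diag(6) * 12
  labs <- rep(1:6, each = 30)
  x <- centers[labs, ] + matrix(rnorm(180 * 6, 0, 0.2), ncol = 6)
  ua <- sort_channel(x, seed = 1)
  expect_equal(ua$chosen_k, 5)  # cap, even with 6 planted clusters
  few <- matrix(rnorm(9 * 3), ncol = 3)
  ua9 <- sort_channel(few, seed = 1)
  expect_equal(ua9$chosen_k, 1)
  expect_error(sort_channel(matrix(numeric(0), 0, 3)), "empty")
})

test_that("sorting is reproducible under a fixed seed", {
  pc <- local({ set.seed(47); planted_unit_snippets(3) })
  feats <- snippet_features(pc$snippets, 25000)
  a <- sort_channel(feats, seed = 9)
  b <- sort_channel(feats, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$silhouette_by_k, b$silhouette_by_k)
})

test_that("waveform-level sorting recovers planted units on a channel", {
  set.seed(48)
  pc <- planted_unit_snippets(3, n_per = 60, noise_sd = 5)
  feats <- snippet_features(pc$snippets, 25000)
  ua <- sort_channel(feats, seed = 2)
  expect_equal(ua$chosen_k, 3)
  expect_gte(adjusted_rand_index(pc$labels, ua$labels), 0.95)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(49)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)
})
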