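test_that("PSTH binning follows the centred-bin convention", {
  # one spike 15.4 ms after a single stimulus lands in bin 15
  p <- build_psth(10 + 15.4e-3, 10)
  expect_equal(length(p$counts), 500)
  expect_equal(p$bins, -50:449)
  expect_equal(p$counts[p$bins == 15], 1)
  expect_equal(sum(p$counts), 1)
  # boundary convention: -50.0 ms included, +450.0 ms excluded
  pb <- build_psth(c(10 - 50e-3, 10 + 450e-3), 10)
  expect_equal(sum(pb$counts), 1)
  expect_equal(pb$counts[pb$bins == -50], 1)
  # 100 stimuli with one spike 15 ms after each -> bin 15 holds 100
  stim <- seq(0, by = 0.7, length.out = 100)
  p100 <- build_psth(stim + 15e-3, stim)
  expect_equal(p100$counts[p100$bins == 15], 100)
  expect_error(build_psth(1, numeric(0)), "no stimuli")
})

test_that("PSTH conserves spikes within the peri-stimulus window", {
  set.seed(12)
  stim <- sort(runif(50, 10, 60))
  spikes <- sort(runif(2000, 0, 70))
  p <- build_psth(spikes, stim)
  pairs <- 0L
  for (s in stim) {
    rel <- (spikes - s) * 1000
    pairs <- pairs + sum(rel >= -50.5 & rel < 449.5)
  }
  expect_equal(sum(p$counts), pairs)
})

test_that("background subtraction zeroes the pre-stimulus window mean", {
  p <- make_psth(rep(3, 500))
  s <- subtract_background(p)
  expect_true(all(abs(s$counts) < 1e-12))
  expect_error(subtract_background(s), "already subtracted")
  # empty background window subtracts zero, leaving the PSTH unchanged
  p0 <- make_psth(c(numeric(100), rep(2, 400)))
  s0 <- subtract_background(p0)
  expect_equal(s0$counts, p0$counts)
  # post-subtraction background mean is 0 by construction
  set.seed(3)
  pr <- make_psth(rpois(500, 4))
  sr <- subtract_background(pr)
  bg <- sr$bins >= -50 & sr$bins <= -5
  expect_equal(mean(sr$counts[bg]), 0, tolerance = 1e-12)
})

test_that("peak amplitude is the window maximum", {
  cnt <- numeric(500)
  cnt[51 + 15] <- 37  # bin labelled 15
  cnt[51 + 30] <- 50  # bin labelled 30 (late window)
  p <- make_psth(cnt)
  expect_equal(peak_amplitude(p, c(10, 19)), 37)
  expect_equal(peak_amplitude(p, c(21, 35)), 50)
  expect_equal(peak_amplitude(make_psth(numeric(500))), 0)
  expect_error(peak_amplitude(p, c(400, 460)), "outside")
  expect_identical(analysis_windows()$early, c(10L, 19L))
  expect_identical(analysis_windows()$late, c(21L, 35L))
})

test_that("center of mass matches hand-computable cases and the oracle", {
  cnt <- numeric(500)
  cnt[51 + 15] <- 12
  p <- make_psth(cnt)
  expect_equal(center_of_mass(p, c(10, 19)), 15)
  # equal mass at bins 21 and 35 -> midpoint 28
  cnt2 <- numeric(500)
  cnt2[51 + 21] <- 7
  cnt2[51 + 35] <- 7
  expect_equal(center_of_mass(make_psth(cnt2), c(21, 35)), 28)
  # zero mass -> NA
  expect_true(is.na(center_of_mass(make_psth(numeric(500)), c(10, 19))))
  # random vectors against the brute-force weighted mean
  set.seed(21)
  for (i in 1:20) {
    cnt3 <- numeric(500)
    cnt3[51 + (10:19)] <- rpois(10, 5)
    p3 <- make_psth(cnt3)
    expect_equal(center_of_mass(p3, c(10, 19)),
                 brute_force_com(p3$counts, p3$bins, 10, 19),
                 tolerance = 1e-9)
  }
})

test_that("negative bins are clipped in the CoM weights by default", {
  cnt <- numeric(500)
  cnt[51 + 15] <- 10
  cnt[51 + 19] <- -4
  p <- make_psth(cnt)
  p$background_subtracted <- TRUE
  expect_equal(center_of_mass(p, c(10, 19)), 15)
  expect_equal(center_of_mass(p, c(10, 19), clip_negative = FALSE),
               (10 * 15 - 4 * 19) / 6)
})

test_that("PSTH averaging is the per-bin arithmetic mean", {
  a <- make_psth(rep(2, 500))
  b <- make_psth(rep(4, 500))
  m <- average_psths(list(a, b))
  expect_equal(m$counts, rep(3, 500))
  expect_identical(average_psths(list(a, a))$counts, a$counts)
  # mixing raw and subtracted PSTHs is an error
  expect_error(average_psths(list(a, subtract_background(b))), "mix")
  short <- build_psth(numeric(0), 0, t_pre_ms = 10, t_post_ms = 40)
  expect_error(average_psths(list(a, short)), "mismatched bins")
})

test_that("background subtraction and averaging commute", {
  set.seed(31)
  ps <- lapply(1:3, function(i) make_psth(rpois(500, 6)))
  a <- subtract_background(average_psths(ps))
  b <- average_psths(lapply(ps, subtract_background))
  expect_equal(a$counts, b$counts, tolerance = 1e-12)
})

test_that("conduction velocity arithmetic and guards", {
  expect_equal(conduction_velocity(15, 0.9), 60)
  expect_equal(conduction_velocity(15, 1.8), 120)  # doubling distance
  expect_equal(conduction_velocity(20, 0.9, offset_ms = 5), 60)
  expect_error(conduction_velocity(15, 0), "distance")
  expect_error(conduction_velocity(5, 0.9, offset_ms = 5), "latency")
})

test_that("simulated early peak yields CoM near the planted latency", {
  cfg <- sim_config(seed = 91, n_channels = 1, layer_of_channel = "IV",
                    sessions_pre = 1, sessions_post = 0, burst_rate = 0)
  ex <- simulate_experiment(cfg)
  stim <- ex$schedule$time_s  # 200 stimuli, both nerves pooled
  p <- subtract_background(build_psth(ex$spikes$time_s, stim))
  expect_lt(abs(center_of_mass(p, c(10, 19)) - 15), 0.5)
  # amplitude grows with planted gain
  cfg2 <- sim_config(seed = 91, n_channels = 1, layer_of_channel = "IV",
                     sessions_pre = 1, sessions_post = 0, burst_rate = 0,
                     early_gain_by_layer = c(I = 0, II = 0, III = 0,
                                             IV = 3.6, V = 0, VI = 0))
  ex2 <- simulate_experiment(cfg2)
  p2 <- subtract_background(build_psth(ex2$spikes$time_s,
                                       ex2$schedule$time_s))
  expect_gt(peak_amplitude(p2, c(10, 19)), peak_amplitude(p, c(10, 19)))
})
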