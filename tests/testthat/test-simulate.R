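test_that("stimulus schedule alternates nerves at the nominal rate", {
  cfg <- sim_config(seed = 3, sessions_pre = 1, sessions_post = 0)
  sch <- generate_stimulus_schedule(cfg)
  expect_equal(nrow(sch), 200)
  expect_equal(unname(table(sch$nerve)), c(100L, 100L), ignore_attr = TRUE)
  expect_true(all(sch$nerve[seq(1, 199, 2)] != sch$nerve[seq(2, 200, 2)]))
  expect_true(all(diff(sch$time_s) > 0))
  expect_true(all(sch$pre) && all(sch$phase == 0))
})

test_that("schedule respects session structure and phase grouping", {
  cfg <- sim_config(seed = 5, sessions_pre = 3, sessions_post = 18)
  sch <- generate_stimulus_schedule(cfg)
  expect_equal(nrow(sch), 21 * 200)
  expect_equal(sort(unique(sch$phase)), 0:6)
  expect_equal(unname(table(sch$phase[!duplicated(sch$session)])),
               c(3L, rep(3L, 6)), ignore_attr = TRUE)
  # sessions start 10 min apart
  starts <- tapply(sch$time_s, sch$session, min)
  expect_true(all(abs(diff(starts) - 600) < 0.2))
})

test_that("degenerate schedules behave as specified", {
  cfg0 <- sim_config(seed = 1, sessions_pre = 0, sessions_post = 0)
  expect_equal(nrow(generate_stimulus_schedule(cfg0)), 0)
  cfgj <- sim_config(seed = 1, sessions_pre = 1, sessions_post = 0,
                     isi_jitter_ms = 0)
  sch <- generate_stimulus_schedule(cfgj)
  expect_equal(diff(sch$time_s), rep(0.5, 199), tolerance = 1e-12)
  expect_error(sim_config(stim_rate = 0), "stim_rate")
  expect_error(sim_config(stimuli_per_session = 0), "stimuli_per_session")
  expect_error(sim_config(n_channels = 4, layer_of_channel = c("I", "II")),
               "layer_of_channel")
})

test_that("spike trains are empty when all rates are zero", {
  cfg <- sim_config(seed = 2, n_channels = 2,
                    layer_of_channel = c("III", "IV"),
                    sessions_pre = 1, sessions_post = 0,
                    background_rate = 0, burst_rate = 0,
                    early_gain_by_layer = c(I = 0, II = 0, III = 0, IV = 0,
                                            V = 0, VI = 0),
                    late_gain_by_layer = c(I = 0, II = 0, III = 0, IV = 0,
                                           V = 0, VI = 0))
  ex <- simulate_experiment(cfg)
  expect_equal(nrow(ex$spikes), 0)
})

test_that("background-only counts stay inside the Poisson 99% interval", {
  cfg <- sim_config(seed = 7, n_channels = 1, layer_of_channel = "V",
                    background_rate = 10, burst_rate = 0)
  tr <- generate_spike_trains(cfg, NULL, duration_s = 10)
  lam <- 10 * 10
  expect_gte(nrow(tr$spikes), qpois(0.005, lam))
  expect_lte(nrow(tr$spikes), qpois(0.995, lam))
})

test_that("empirical background rate converges to the configured rate", {
  cfg <- sim_config(seed = 11, n_channels = 16,
                    layer_of_channel = rep(c("V", "VI"), 8),
                    background_rate = 8, burst_rate = 0)
  tr <- generate_spike_trains(cfg, NULL, duration_s = 100)
  rate <- nrow(tr$spikes) / (16 * 100)
  expect_lt(abs(rate - 8) / 8, 0.05)
})

test_that("bursts occur only on layer III-IV channels", {
  cfg <- sim_config(seed = 13, n_channels = 4,
                    layer_of_channel = c("I", "III", "IV", "V"),
                    background_rate = 2, burst_rate = 0.2,
                    burst_peak_rate = 250)
  tr <- generate_spike_trains(cfg, NULL, duration_s = 60)
  by_source <- table(tr$spikes$channel[tr$spikes$source == "burst"])
  expect_true(all(names(by_source) %in% c("2", "3")))
  expect_gt(sum(by_source), 0)
})

test_that("identical seeds reproduce spike trains; different seeds differ", {
  cfg <- sim_config(seed = 21, n_channels = 2,
                    layer_of_channel = c("III", "IV"),
                    sessions_pre = 1, sessions_post = 0)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$spikes, b$spikes)
  cfg2 <- sim_config(seed = 22, n_channels = 2,
                     layer_of_channel = c("III", "IV"),
                     sessions_pre = 1, sessions_post = 0)
  c_ <- simulate_experiment(cfg2)
  expect_false(identical(a$spikes$time_s, c_$spikes$time_s))
})

test_that("per-unit refractory period is honoured", {
  cfg <- sim_config(seed = 17, n_channels = 1, layer_of_channel = "IV",
                    background_rate = 200, burst_rate = 0,
                    units_per_channel = 2, refractory_ms = 1)
  tr <- generate_spike_trains(cfg, NULL, duration_s = 20)
  for (u in unique(tr$spikes$unit)) {
    tu <- sort(tr$spikes$time_s[tr$spikes$unit == u])
    expect_true(all(diff(tu) >= 0.001 - 1e-12))
  }
})

test_that("pooled PSTH of simulated trains peaks at the planted latency", {
  cfg <- sim_config(seed = 31, n_channels = 1, layer_of_channel = "IV",
                    sessions_pre = 3, sessions_post = 3,
                    background_rate = 2, burst_rate = 0)
  ex <- simulate_experiment(cfg)
  p <- build_psth(ex$spikes$time_s, ex$schedule$time_s)  # >=1000 stimuli
  peak_bin <- p$bins[which.max(p$counts)]
  expect_lte(abs(peak_bin - 15), 1)
})

test_that("post/pre evoked-count ratio converges to the injury multiplier", {
  cfg <- sim_config(seed = 41, n_channels = 1, layer_of_channel = "III",
                    sessions_pre = 3, sessions_post = 6,
                    background_rate = 0, burst_rate = 0,
                    late_gain_by_layer = c(I = 0, II = 0, III = 0, IV = 0,
                                           V = 0, VI = 0))
  ex <- simulate_experiment(cfg)
  win <- ex$spikes$source == "early"
  n_pre <- sum(win & ex$spikes$phase == 0) / 3
  n_post <- sum(win & ex$spikes$phase > 0) / 6
  expect_lt(abs(n_post / n_pre - 1.46), 0.15)
})

test_that("continuous rendering is the linear sum of templates plus noise", {
  cfg <- sim_config(seed = 51, n_channels = 1, layer_of_channel = "V",
                    noise_sd = 0, units_per_channel = 1)
  tpl <- waveform_template(cfg$sampling_rate, neg_amp = 100, pos_amp = 35)
  one <- data.frame(time_s = 0.05, channel = 1L, unit = 1L)
  rec <- generate_continuous(cfg, one, duration_s = 0.1,
                             templates = list(tpl))
  pk <- attr(tpl, "peak_index")
  i0 <- round(0.05 * cfg$sampling_rate) + 1 - (pk - 1)
  expect_equal(rec$samples[i0:(i0 + length(tpl) - 1), 1], as.numeric(tpl))
  expect_true(all(rec$samples[-(i0:(i0 + length(tpl) - 1)), 1] == 0))

  # two coincident spikes add sample-wise
  two <- data.frame(time_s = c(0.05, 0.05), channel = c(1L, 1L),
                    unit = c(1L, 1L))
  rec2 <- generate_continuous(cfg, two, duration_s = 0.1,
                              templates = list(tpl))
  expect_equal(rec2$samples[, 1], 2 * rec$samples[, 1])

  # spike outside the trace errors
  expect_error(generate_continuous(cfg, data.frame(time_s = 0.2,
                                                   channel = 1L, unit = 1L),
                                   duration_s = 0.1, templates = list(tpl)),
               "beyond trace duration")
})

test_that("noise-only trace RMS matches the configured noise SD", {
  cfg <- sim_config(seed = 61, n_channels = 2,
                    layer_of_channel = c("III", "IV"), noise_sd = 12)
  rec <- generate_continuous(cfg, data.frame(time_s = numeric(0),
                                             channel = integer(0),
                                             unit = integer(0)),
                             duration_s = 2)
  rms <- sqrt(mean(rec$samples^2))
  expect_lt(abs(rms - 12) / 12, 0.01)
})
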