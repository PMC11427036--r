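test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(tau_ms = 10, duration_s = 5, base_rate_hz = 20,
                    n_trains = 2, seed = 7)
  a <- simulate_timescale_train(cfg)
  b <- simulate_timescale_train(cfg)
  expect_identical(a$raster$counts, b$raster$counts)
  expect_identical(a$probability, b$probability)
  cfg2 <- cfg; cfg2$seed <- 8
  expect_false(identical(simulate_timescale_train(cfg2)$raster$counts,
                         a$raster$counts))
  # seeded calls must not disturb the session RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_timescale_train(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("realized firing rate matches the target within 5%", {
  # smooth-latent regime (no clipping) at the default 1.9 Hz unit rate
  sim <- simulate_timescale_train(sim_config(
    tau_ms = 20, duration_s = 600, base_rate_hz = 1.9, seed = 1))
  rate <- sum(sim$raster$counts) / 600
  expect_lt(abs(rate - 1.9) / 1.9, 0.05)
  # sparse-input regime where single kernels clip at 1: the post-clip
  # rescale must still deliver the target rate
  sim2 <- simulate_timescale_train(sim_config(
    tau_ms = 5, duration_s = 600, base_rate_hz = 20, input_rate_hz = 2,
    seed = 2))
  expect_gt(max(sim2$probability), 0.99)        # clipping actually engaged
  rate2 <- sum(sim2$raster$counts) / 600
  expect_lt(abs(rate2 - 20) / 20, 0.05)
})

test_that("zero modulation is the identity and the mean probability is exact", {
  base <- simulate_timescale_train(sim_config(
    tau_ms = 10, duration_s = 20, base_rate_hz = 5, seed = 3))
  with_osc0 <- simulate_timescale_train(sim_config(
    tau_ms = 10, duration_s = 20, base_rate_hz = 5, osc_freq_hz = 3,
    osc_strength = 0, seed = 3))
  expect_identical(base$probability, with_osc0$probability)
  expect_equal(mean(base$probability), 5 / 1000, tolerance = 1e-12)
  # additive modulation shifts the trace by exactly the stated sine
  mod <- simulate_timescale_train(sim_config(
    tau_ms = 10, duration_s = 20, base_rate_hz = 5, osc_freq_hz = 3,
    osc_strength = 0.5, seed = 3))
  expected <- base$probability +
    0.5 * mean(base$probability) * sin(2 * pi * 3 * base$time_s)
  expect_equal(mod$probability, pmin(pmax(expected, 0), 1))
})

test_that("invalid configurations are rejected and sparse ones warned about", {
  expect_error(sim_config(tau_ms = -1), "tau_ms")
  expect_error(sim_config(tau_ms = 10, osc_freq_hz = 600, osc_strength = 0.5),
               "Nyquist")
  expect_error(sim_config(tau_ms = 10, osc_strength = 1.5), "osc_strength")
  expect_warning(
    simulate_timescale_train(sim_config(tau_ms = 10, duration_s = 5,
                                        base_rate_hz = 1, seed = 1)),
    "unstable")
})

test_that("spike rasters are binary per train and probabilities are in [0,1]", {
  sim <- simulate_timescale_train(sim_config(
    tau_ms = 5, duration_s = 5, base_rate_hz = 50, n_trains = 3, seed = 4))
  expect_true(all(sim$raster$counts %in% c(0L, 1L)))
  expect_equal(dim(sim$raster$counts), c(3L, 5000L))
  expect_true(all(sim$probability >= 0 & sim$probability <= 1))
})

test_that("MEA simulation plants recoverable network events", {
  cfg <- sim_config(tau_ms = 10, fs_hz = 1000, duration_s = 300,
                    base_rate_hz = 20, seed = 11)
  mea <- simulate_mea_recording(cfg, n_channels = 16,
                                burst_rate_hz = 10 / 300,
                                burst_duration_s = 1)
  expect_length(mea$onsets_s, 10)
  pop <- population_vector(rebin_raster(mea$raster, 0.1))
  ev <- detect_network_events(pop)
  expect_equal(nrow(ev), 10)
  expect_true(all(abs(ev$onset_s - floor(mea$onsets_s / 0.1) * 0.1) <=
                    0.1 + 1e-9))
  # silent case
  mea0 <- simulate_mea_recording(cfg, n_channels = 4, burst_rate_hz = 0,
                                 background_rate_hz = 0)
  pop0 <- population_vector(rebin_raster(mea0$raster, 0.1))
  expect_equal(nrow(detect_network_events(pop0)), 0)
  # reproducibility
  mea2 <- simulate_mea_recording(cfg, n_channels = 16,
                                 burst_rate_hz = 10 / 300,
                                 burst_duration_s = 1)
  expect_identical(mea$raster$counts, mea2$raster$counts)
})

test_that("developmental studies honor their ground-truth family", {
  # constant truth with zero jitter: one shared tau everywhere
  cfg <- trajectory_study_config(
    timepoints = c(1, 5, 9, 13), family = "constant",
    family_params = list(c = 25), channels_per_timepoint = 4,
    noise_sd_ms = 0, seed = 1)
  st <- simulate_study(cfg, generate_spikes = FALSE)
  expect_true(all(st$truth$tau_ms_true == 25))
  expect_equal(nrow(st$truth), 16)
  # determinism of truth tables
  st2 <- simulate_study(cfg, generate_spikes = FALSE)
  expect_identical(st$truth, st2$truth)
  # nonpositive tau(t) rejected at config time
  expect_error(trajectory_study_config(
    timepoints = c(1, 5), family = "sigmoid",
    family_params = list(a = -10, b = 2, t0 = 3, s = 1)), "positive")
  expect_error(trajectory_study_config(
    timepoints = c(5, 1), family = "constant", family_params = list(c = 1)),
    "increasing")
  # heavy jitter around a tiny tau: resampling still yields positive taus
  noisy <- trajectory_study_config(
    timepoints = c(1, 5), family = "constant", family_params = list(c = 1e-4),
    channels_per_timepoint = 20, noise_sd_ms = 50, seed = 2)
  st3 <- simulate_study(noisy, generate_spikes = FALSE)
  expect_true(all(st3$truth$tau_ms_true > 0))
})

test_that("trajectory family curves have their defining shapes", {
  t <- seq(0, 100, by = 5)
  expect_equal(tau_trajectory("constant", list(c = 7), t), rep(7, length(t)))
  sig <- tau_trajectory("sigmoid", list(a = 2, b = 10, t0 = 50, s = 8), t)
  expect_equal(sig[t == 50], 2 + 5)              # midpoint = a + b/2
  expect_true(all(diff(sig) > 0))
  gau <- tau_trajectory("gaussian", list(a = 10, mu = 40, sigma = 15, c = 2), t)
  expect_equal(max(gau), gau[t == 40])
  expect_equal(gau[t == 40], 12)
})
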