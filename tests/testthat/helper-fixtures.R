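# Shared fixture builders (all fixtures are generated in code).

# Gaussian noise trace with sharp transients of known amplitude inserted at
# known sample indices; oracle for the adaptive-threshold spike detector.
make_transient_trace <- function(n, fs_hz, insert_at, amplitude = 10,
                                 seed = 42) {
  set.seed(seed)
  x <- rnorm(n)
  x[insert_at] <- amplitude
  raw_recording(rbind(x, rnorm(n)), fs_hz,
                channel_ids = c("probe", "noise"))
}

# Quick latent-trace simulation + spectral timescale estimate.
sim_spectral_tau <- function(tau_ms, seed, duration_s = 60, rate = 20,
                             osc_freq_hz = 0, osc_strength = 0) {
  sim <- simulate_timescale_train(sim_config(
    tau_ms = tau_ms, duration_s = duration_s, base_rate_hz = rate,
    osc_freq_hz = osc_freq_hz, osc_strength = osc_strength, seed = seed))
  estimate_tau_spectral(sim$probability, sim$cfg$fs_hz)
}

# Truth-table-only developmental study -> gaussian-vs-constant F test.
study_f_pvalue <- function(family, params, seed, noise_sd_ms,
                           timepoints = seq(100, 350, length.out = 15),
                           channels = 32, test_family = "gaussian") {
  cfg <- trajectory_study_config(
    timepoints = timepoints, family = family, family_params = params,
    channels_per_timepoint = channels, noise_sd_ms = noise_sd_ms,
    seed = seed)
  st <- simulate_study(cfg, generate_spikes = FALSE)
  est <- data.frame(timepoint_days = st$truth$timepoint,
                    tau_ms = st$truth$tau_ms_true)
  agg <- aggregate_trajectory(est)
  f_test(fit_trajectory(agg, "constant"),
         fit_trajectory(agg, test_family))$p_value
}

# Bare trajectory_fit stub with prescribed rss/df, for F-ratio arithmetic.
fit_stub <- function(family, rss, n_points, n_params) {
  structure(list(family = family, params = list(), rss = rss,
                 n_points = n_points, n_params = n_params,
                 fitted = function(t) rep(NA_real_, length(t)),
                 converged = TRUE),
            class = "trajectory_fit")
}
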