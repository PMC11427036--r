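#' Simulation configuration
#'
#' Parameters for simulating population spiking with a known intrinsic
#' timescale. A homogeneous Poisson population impulse train (rate
#' `input_rate_hz`, the pooled rate of the presynaptic population) is
#' convolved with an exponentially decaying synaptic kernel
#' `exp(-t/tau)`; the convolved trace, rescaled to a spiking probability
#' per sample, is the latent "synaptic activity" signal whose power
#' spectrum is Lorentzian with knee frequency `1/(2*pi*tau)`. Spike trains
#' are Bernoulli-sampled from the probability trace.
#'
#' @param tau_ms ground-truth kernel decay constant, milliseconds (> 0).
#' @param fs_hz simulation sampling rate, Hz. The default 1000 Hz resolves
#'   knee frequencies up to the 100-Hz outlier bound used downstream.
#' @param duration_s trace length, seconds.
#' @param base_rate_hz target mean firing rate per output train, Hz. The
#'   default 1.9 Hz matches the average single-unit rate of the dissociated
#'   -culture recordings this simulator emulates.
#' @param n_trains number of Bernoulli spike trains drawn from the shared
#'   population probability trace.
#' @param osc_freq_hz frequency of an optional sine modulation of the
#'   spiking probability, Hz (0 = none). Must be below `fs_hz / 2`.
#' @param osc_strength dimensionless modulation depth in `[0, 1]`.
#' @param osc_mode `"additive"` (default; sine of amplitude
#'   `osc_strength * mean(p)` is added to the probability trace) or
#'   `"multiplicative"` (`p * (1 + osc_strength * sin)`); both are clipped
#'   to `[0, 1]` before sampling.
#' @param input_rate_hz pooled Poisson input rate, Hz. Default 2000 Hz
#'   (1000 presynaptic neurons at 2 Hz), which yields a smooth latent trace.
#' @param seed integer RNG seed, or `NULL` to use the session stream.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(tau_ms, fs_hz = 1000, duration_s = 60,
                       base_rate_hz = 1.9, n_trains = 1,
                       osc_freq_hz = 0, osc_strength = 0,
                       osc_mode = c("additive", "multiplicative"),
                       input_rate_hz = 2000, seed = NULL) {
  osc_mode <- match.arg(osc_mode)
  if (!is.numeric(tau_ms) || length(tau_ms) != 1L || tau_ms <= 0)
    stop("'tau_ms' must be a single positive number")
  if (fs_hz <= 0) stop("'fs_hz' must be positive")
  if (duration_s <= 0) stop("'duration_s' must be positive")
  if (base_rate_hz <= 0) stop("'base_rate_hz' must be positive")
  if (base_rate_hz >= fs_hz)
    stop("'base_rate_hz' must be below 'fs_hz' (at most one spike per sample)")
  if (input_rate_hz <= 0) stop("'input_rate_hz' must be positive")
  if (osc_strength < 0 || osc_strength > 1)
    stop("'osc_strength' must lie in [0, 1]")
  if (osc_strength > 0 && osc_freq_hz >= fs_hz / 2)
    stop("'osc_freq_hz' must be below the Nyquist frequency fs_hz/2")
  if (n_trains < 1) stop("'n_trains' must be >= 1")
  structure(list(tau_ms = tau_ms, fs_hz = fs_hz, duration_s = duration_s,
                 base_rate_hz = base_rate_hz, n_trains = as.integer(n_trains),
                 osc_freq_hz = osc_freq_hz, osc_strength = osc_strength,
                 osc_mode = osc_mode, input_rate_hz = input_rate_hz,
                 seed = seed),
            class = "sim_config")
}

# Exponential synaptic kernel, sampled at fs, truncated at 10*tau,
# peak-normalized. Only the decay shape matters for the timescale; absolute
# scale is absorbed by the probability rescaling.
exp_kernel <- function(tau_ms, fs_hz) {
  n <- max(2L, ceiling(10 * (tau_ms / 1000) * fs_hz))
  exp(-(seq_len(n) - 1L) / (tau_ms / 1000 * fs_hz))
}

# FFT convolution padded to a 2-3-5-smooth length (convolve()'s "open"
# mode can land on a prime-length transform and degrade to O(n^2)).
fft_convolve <- function(x, kern) {
  n <- length(x)
  m <- stats::nextn(n + length(kern) - 1L, c(2, 3, 5))
  xp <- c(x, numeric(m - n))
  kp <- c(kern, numeric(m - length(kern)))
  out <- Re(fft(fft(xp) * fft(kp), inverse = TRUE)) / m
  out[seq_len(n)]
}

# Scale a nonnegative trace so that mean(pmin(scale * x, 1)) == target,
# accounting for clipping (bisection; mean is monotone in scale).
scale_to_mean <- function(x, target) {
  mx <- mean(x)
  if (mx == 0) return(x)
  s <- target / mx
  p <- pmin(s * x, 1)
  if (max(s * x) <= 1) return(p)           # no clipping: exact already
  lo <- s; hi <- s
  while (mean(pmin(hi * x, 1)) < target) {
    hi <- hi * 2
    if (hi > 1e12) stop("target rate unreachable after clipping")
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (mean(pmin(mid * x, 1)) < target) lo <- mid else hi <- mid
  }
  pmin(((lo + hi) / 2) * x, 1)
}

#' Simulate spike trains with a known timescale
#'
#' Draws a Poisson population impulse train, convolves it with the
#' exponential kernel defined by `cfg$tau_ms`, rescales the result to a
#' per-sample spiking probability with mean `base_rate_hz / fs_hz`
#' (rescaling accounts for clipping at 1, so the realized rate matches the
#' target within sampling error), optionally applies a sine modulation, and
#' Bernoulli-samples `n_trains` spike trains from the shared probability
#' trace.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `timescale_sim` with elements `raster` (a
#'   [spike_raster()], `n_trains` rows of 0/1 counts at 1-sample bins),
#'   `probability` (the latent probability trace actually sampled from),
#'   `time_s`, and `cfg`.
#' @export
simulate_timescale_train <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- round(cfg$duration_s * cfg$fs_hz)
    expected <- cfg$base_rate_hz * cfg$duration_s * cfg$n_trains
    if (expected < 100)
      warning(sprintf(
        "expected spike count %.1f < 100; timescale estimates will be unstable",
        expected))
    impulses <- rpois(n, cfg$input_rate_hz / cfg$fs_hz)
    kern <- exp_kernel(cfg$tau_ms, cfg$fs_hz)
    latent <- fft_convolve(impulses, kern)
    latent[latent < 0] <- 0                  # FFT round-off
    p <- scale_to_mean(latent, cfg$base_rate_hz / cfg$fs_hz)
    if (cfg$osc_strength > 0) {
      t_s <- (seq_len(n) - 1L) / cfg$fs_hz
      s <- sin(2 * pi * cfg$osc_freq_hz * t_s)
      p <- if (cfg$osc_mode == "additive")
        p + cfg$osc_strength * mean(p) * s
      else p * (1 + cfg$osc_strength * s)
      p <- pmin(pmax(p, 0), 1)
    }
    counts <- matrix(as.integer(runif(cfg$n_trains * n) <
                                  rep(p, each = cfg$n_trains)),
                     nrow = cfg$n_trains)
    structure(
      list(raster = spike_raster(counts, 1 / cfg$fs_hz, 0,
                                 ids = paste0("train", seq_len(cfg$n_trains))),
           probability = p,
           time_s = (seq_len(n) - 1L) / cfg$fs_hz,
           cfg = cfg),
      class = "timescale_sim")
  })
}

#' @export
print.timescale_sim <- function(x, ...) {
  cat(sprintf(
    "timescale_sim: tau = %g ms, %d train(s), %g s at %g Hz, %d spikes\n",
    x$cfg$tau_ms, x$cfg$n_trains, x$cfg$duration_s, x$cfg$fs_hz,
    sum(x$raster$counts)))
  invisible(x)
}

#' Simulate an MEA-like recording with network events
#'
#' Generates a multi-channel spike raster in which all channels share
#' planted burst epochs ("network events": elevated common firing at
#' `cfg$base_rate_hz` per channel for `burst_duration_s`) separated by
#' near-silent gaps (`background_rate_hz` per channel), so that half-max
#' event detection on the population vector recovers the planted onsets.
#'
#' @param cfg a [sim_config()]; `fs_hz`, `duration_s`, `base_rate_hz` (the
#'   in-burst per-channel rate) and `seed` are used.
#' @param n_channels number of channels.
#' @param burst_rate_hz expected rate of network events, Hz (>= 0; e.g.
#'   10 events in 300 s is 1/30 Hz). Events are jittered on a regular grid
#'   so they never overlap.
#' @param burst_duration_s duration of the elevated-rate epoch, seconds.
#' @param background_rate_hz per-channel rate between events, Hz.
#' @return A list of class `mea_sim`: `raster` (channels x samples, binary,
#'   1-sample bins), `onsets_s` (planted burst onset times), `cfg`.
#' @export
simulate_mea_recording <- function(cfg, n_channels = 16, burst_rate_hz = 1 / 30,
                                   burst_duration_s = 1,
                                   background_rate_hz = 0.05) {
  stopifnot(inherits(cfg, "sim_config"))
  if (burst_rate_hz < 0) stop("'burst_rate_hz' must be >= 0")
  with_seed(cfg$seed, {
    fs <- cfg$fs_hz
    n <- round(cfg$duration_s * fs)
    n_bursts <- round(burst_rate_hz * cfg$duration_s)
    onsets <- numeric(0)
    if (n_bursts > 0) {
      slot <- cfg$duration_s / n_bursts
      margin <- min(burst_duration_s + 3, slot)  # keep events separated
      if (slot <= burst_duration_s)
        stop("burst_rate_hz too high: events would overlap")
      onsets <- (seq_len(n_bursts) - 1L) * slot +
        runif(n_bursts, 0.5, pmax(0.51, slot - margin))
    }
    rate <- rep(background_rate_hz, n)
    for (o in onsets) {
      i0 <- floor(o * fs) + 1L
      i1 <- min(n, i0 + round(burst_duration_s * fs) - 1L)
      rate[i0:i1] <- cfg$base_rate_hz
    }
    p <- pmin(rate / fs, 1)
    counts <- matrix(as.integer(runif(n_channels * n) <
                                  rep(p, each = n_channels)),
                     nrow = n_channels)
    structure(
      list(raster = spike_raster(counts, 1 / fs, 0,
                                 ids = paste0("ch", seq_len(n_channels))),
           onsets_s = onsets, cfg = cfg),
      class = "mea_sim")
  })
}

#' Ground-truth developmental trajectory families
#'
#' Evaluates the three hypothesized trajectory shapes at times `t`:
#' constant (`c`), sigmoid (`a + b / (1 + exp(-(t - t0)/s))`), and Gaussian
#' (`a * exp(-(t - mu)^2 / (2 * sigma^2)) + c`).
#'
#' @param family one of `"constant"`, `"sigmoid"`, `"gaussian"`.
#' @param params named list/vector of the family's parameters: constant:
#'   `c`; sigmoid: `a`, `b`, `t0`, `s`; gaussian: `a`, `mu`, `sigma`, `c`.
#' @param t numeric vector of times (days).
#' @return Numeric vector of trajectory values at `t`.
#' @export
tau_trajectory <- function(family, params, t) {
  family <- match.arg(family, c("constant", "sigmoid", "gaussian"))
  p <- as.list(params)
  switch(family,
    constant = rep(p$c, length(t)),
    sigmoid  = p$a + p$b / (1 + exp(-(t - p$t0) / p$s)),
    gaussian = p$a * exp(-(t - p$mu)^2 / (2 * p$sigma^2)) + p$c)
}

#' Configuration for a synthetic developmental study
#'
#' @param timepoints strictly increasing vector of recording days.
#' @param family,family_params ground-truth trajectory, see
#'   [tau_trajectory()]; `tau(t)` must be positive at every timepoint.
#' @param channels_per_timepoint number of channels/units per timepoint.
#' @param sim_template a [sim_config()] used as the per-channel template
#'   (its `tau_ms` and `seed` are overridden).
#' @param noise_sd_ms between-channel jitter SD of the ground-truth tau, ms.
#' @param seed study RNG seed.
#' @return A list of class `trajectory_study_config`.
#' @export
trajectory_study_config <- function(timepoints, family, family_params,
                                    channels_per_timepoint = 8,
                                    sim_template = sim_config(tau_ms = 10),
                                    noise_sd_ms = 0, seed = NULL) {
  if (length(timepoints) < 2 || any(diff(timepoints) <= 0))
    stop("'timepoints' must be strictly increasing")
  tau_t <- tau_trajectory(family, family_params, timepoints)
  if (any(tau_t <= 0))
    stop("ground-truth tau(t) must be positive at every timepoint")
  stopifnot(inherits(sim_template, "sim_config"))
  if (noise_sd_ms < 0) stop("'noise_sd_ms' must be >= 0")
  structure(list(timepoints = timepoints, family = family,
                 family_params = as.list(family_params),
                 channels_per_timepoint = as.integer(channels_per_timepoint),
                 sim_template = sim_template, noise_sd_ms = noise_sd_ms,
                 seed = seed),
            class = "trajectory_study_config")
}

#' Simulate a multi-timepoint developmental study
#'
#' For every timepoint and channel, draws a ground-truth timescale
#' `tau(t) + jitter` (jitter resampled up to 50 times if it would make tau
#' nonpositive) and, if `generate_spikes = TRUE`, simulates the
#' corresponding spike train. The returned truth table supports
#' parameter-recovery tests of the whole downstream pipeline.
#'
#' @param cfg a [trajectory_study_config()].
#' @param generate_spikes if `FALSE`, only the ground-truth tau table is
#'   produced (fast path for trajectory-statistics validation).
#' @return A list of class `trajectory_study`: `truth` (data frame
#'   `timepoint`, `channel`, `tau_ms_true`), `sims` (list of lists of
#'   `timescale_sim`, or `NULL`), `cfg`.
#' @export
simulate_study <- function(cfg, generate_spikes = TRUE) {
  stopifnot(inherits(cfg, "trajectory_study_config"))
  with_seed(cfg$seed, {
    tau_t <- tau_trajectory(cfg$family, cfg$family_params, cfg$timepoints)
    rows <- list(); sims <- if (generate_spikes) list() else NULL
    for (i in seq_along(cfg$timepoints)) {
      tp_sims <- list()
      for (ch in seq_len(cfg$channels_per_timepoint)) {
        tau_ch <- tau_t[i] + rnorm(1, 0, cfg$noise_sd_ms)
        tries <- 0L
        while (tau_ch <= 0 && tries < 50L) {
          tau_ch <- tau_t[i] + rnorm(1, 0, cfg$noise_sd_ms)
          tries <- tries + 1L
        }
        if (tau_ch <= 0)
          stop("could not draw a positive tau after 50 retries; ",
               "reduce 'noise_sd_ms'")
        rows[[length(rows) + 1L]] <- data.frame(
          timepoint = cfg$timepoints[i], channel = ch, tau_ms_true = tau_ch)
        if (generate_spikes) {
          tpl <- cfg$sim_template
          tpl$tau_ms <- tau_ch
          tpl$seed <- NULL                    # inherit the study stream
          tp_sims[[ch]] <- simulate_timescale_train(tpl)
        }
      }
      if (generate_spikes) sims[[i]] <- tp_sims
    }
    structure(list(truth = do.call(rbind, rows), sims = sims, cfg = cfg),
              class = "trajectory_study")
  })
}
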