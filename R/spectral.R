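#' Spectral analysis configuration
#'
#' Welch and spectral-parameterization settings. Welch defaults (1.0-s
#' Hamming windows, 0.5-s overlap) follow the standard spiking-PSD recipe;
#' the model-fitting defaults (fit range 0.5-100 Hz, at most 6 peaks,
#' relative peak threshold 2 SD, peak widths 0.5-12 Hz, knee-mode
#' aperiodic) are implementation choices documented in the methods
#' vignette.
#'
#' @param welch_window_s Welch segment length, seconds.
#' @param welch_overlap_s overlap between segments, seconds (must be less
#'   than `welch_window_s`).
#' @param fit_range_hz two-element frequency range for model fitting, Hz;
#'   must exclude 0.
#' @param max_n_peaks maximum number of Gaussian peaks.
#' @param peak_threshold_sd peak detection threshold in SDs of the
#'   flattened spectrum.
#' @param peak_width_limits_hz two-element bandwidth limits for peaks, Hz
#'   (bandwidth is twice the Gaussian SD).
#' @param aperiodic_mode `"knee"` (generalized Lorentzian, the default and
#'   the form the timescale is derived from) or `"fixed"` (pure power law).
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(welch_window_s = 1.0, welch_overlap_s = 0.5,
                            fit_range_hz = c(0.5, 100), max_n_peaks = 6,
                            peak_threshold_sd = 2.0,
                            peak_width_limits_hz = c(0.5, 12),
                            aperiodic_mode = c("knee", "fixed")) {
  aperiodic_mode <- match.arg(aperiodic_mode)
  if (welch_overlap_s >= welch_window_s)
    stop("'welch_overlap_s' must be less than 'welch_window_s'")
  if (length(fit_range_hz) != 2L || fit_range_hz[1] <= 0 ||
      fit_range_hz[1] >= fit_range_hz[2])
    stop("'fit_range_hz' must be increasing and exclude 0 Hz")
  if (length(peak_width_limits_hz) != 2L ||
      peak_width_limits_hz[1] <= 0 ||
      peak_width_limits_hz[1] >= peak_width_limits_hz[2])
    stop("'peak_width_limits_hz' must be positive and increasing")
  structure(list(welch_window_s = welch_window_s,
                 welch_overlap_s = welch_overlap_s,
                 fit_range_hz = fit_range_hz, max_n_peaks = max_n_peaks,
                 peak_threshold_sd = peak_threshold_sd,
                 peak_width_limits_hz = peak_width_limits_hz,
                 aperiodic_mode = aperiodic_mode),
            class = "spectral_config")
}

#' Welch power spectral density
#'
#' One-sided PSD averaged over Hamming-tapered, overlapping segments, each
#' mean-subtracted before tapering. Satisfies Parseval's relation: the
#' integral of the PSD approximates the signal variance.
#'
#' @param x numeric signal (e.g. a binned spike-count vector or a latent
#'   synaptic-activity trace).
#' @param fs_hz sampling rate of `x`, Hz.
#' @param cfg a [spectral_config()] supplying window and overlap.
#' @param source optional source identifier carried in the result.
#' @return Object of class `power_spectrum`: `freqs_hz` (excluding DC),
#'   `power` (linear units), `fs_hz`, `n_segments`, `source`.
#' @export
welch_psd <- function(x, fs_hz, cfg = spectral_config(), source = NA) {
  x <- as.numeric(x)
  L <- round(cfg$welch_window_s * fs_hz)
  if (length(x) < L)
    stop("signal shorter than one Welch window")
  hop <- L - round(cfg$welch_overlap_s * fs_hz)
  if (hop < 1) stop("overlap too large")
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1L) / (L - 1L))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  acc <- numeric(L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg))^2
  }
  acc <- acc / length(starts) / (fs_hz * sum(w^2))
  nf <- floor(L / 2)
  power <- acc[2:(nf + 1L)] * 2
  if (L %% 2L == 0L) power[nf] <- power[nf] / 2   # Nyquist bin not doubled
  structure(list(freqs_hz = (1:nf) * fs_hz / L, power = power,
                 fs_hz = fs_hz, n_segments = length(starts), source = source),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("power_spectrum: %d bins, %g-%g Hz, %d segment(s) averaged\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              x$n_segments))
  invisible(x)
}

#' Average power spectra in linear power
#'
#' Used to pool per-event segment spectra for a channel before model
#' fitting. All spectra must share a frequency grid.
#'
#' @param psds list of `power_spectrum` objects.
#' @return A `power_spectrum` with element-wise mean power.
#' @export
average_psd <- function(psds) {
  stopifnot(length(psds) > 0, all(vapply(psds, inherits, TRUE,
                                         "power_spectrum")))
  f0 <- psds[[1]]$freqs_hz
  for (p in psds)
    if (length(p$freqs_hz) != length(f0) || any(abs(p$freqs_hz - f0) > 1e-9))
      stop("spectra must share a frequency grid")
  out <- psds[[1]]
  out$power <- rowMeans(vapply(psds, `[[`, numeric(length(f0)), "power"))
  out$n_segments <- sum(vapply(psds, `[[`, numeric(1), "n_segments"))
  out
}

# Generalized Lorentzian aperiodic component in log10 power:
# L(f) = offset - log10(knee + f^exponent); "fixed" mode drops the knee.
aperiodic_curve <- function(f, offset, knee, exponent,
                            mode = "knee") {
  if (mode == "knee") offset - log10(knee + f^exponent)
  else offset - exponent * log10(f)
}

gaussian_curve <- function(f, center, height, sd_hz) {
  height * exp(-(f - center)^2 / (2 * sd_hz^2))
}

# Least-squares aperiodic fit of log10 power; multi-start over knee and
# exponent inits with box constraints in (b, log knee, log exponent) space.
fit_aperiodic <- function(f, y, mode = "knee", init = NULL) {
  if (mode == "fixed") {
    fit <- lm(y ~ log10(f))
    b <- unname(coef(fit))
    par <- c(offset = b[1], knee = NA_real_, exponent = -b[2])
    rss <- sum(fit$residuals^2)
    return(list(params = par, rss = rss))
  }
  obj <- function(th) {
    r <- y - (th[1] - log10(exp(th[2]) + f^exp(th[3])))
    sum(r * r)
  }
  lower <- c(-Inf, log(1e-8), log(0.01))
  upper <- c(Inf, log(1e9), log(10))
  slope <- -(y[length(y)] - y[1]) /
    (log10(f[length(f)]) - log10(f[1]))
  chi0 <- min(9.5, max(0.3, slope))
  starts <- list()
  if (!is.null(init) && is.finite(init[2]) && init[2] > 0)
    starts <- list(unname(c(init[1], log(init[2]),
                            log(max(0.02, init[3])))))
  for (k0 in c(0.1, 1, 10, 100, 1000))
    for (c0 in unique(c(chi0, 2)))
      starts[[length(starts) + 1L]] <-
        c(y[1] + log10(k0 + f[1]^c0), log(k0), log(c0))
  best <- NULL
  for (s in starts) {
    r <- tryCatch(nlminb(s, obj, lower = lower, upper = upper,
                         control = list(iter.max = 500)),
                  error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$objective < best$objective))
      best <- r
  }
  if (is.null(best)) stop("aperiodic fit failed to converge")
  par <- unname(best$par)
  list(params = c(offset = par[1], knee = exp(par[2]),
                  exponent = exp(par[3])),
       rss = best$objective)
}

# Robust refit: drop points lying clearly above the initial aperiodic
# curve (putative peak regions) and refit on the lower envelope.
robust_aperiodic <- function(f, y, mode, first) {
  resid <- y - aperiodic_curve(f, first$params[1], first$params[2],
                               first$params[3], mode)
  flat <- pmax(resid, 0)
  thr <- quantile(flat, 0.025, names = FALSE)
  keep <- flat <= thr
  if (sum(keep) < 5) return(first)
  fit_aperiodic(f[keep], y[keep], mode, init = first$params)
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Decomposes the log10 power spectrum over the fit range into a
#' generalized Lorentzian aperiodic component
#' `L(f) = offset - log10(knee + f^exponent)` plus a sum of Gaussian
#' peaks. The algorithm is iterative: a robust initial aperiodic fit, peak
#' detection on the flattened spectrum (largest first, relative threshold,
#' up to `max_n_peaks`), a joint Gaussian refit, then a final aperiodic
#' refit on the peak-subtracted spectrum. The knee frequency is
#' `f_k = knee^(1/exponent)` and the associated timescale is
#' `tau = 1/(2*pi*f_k)` (see [tau_from_knee()]).
#'
#' @param psd a [welch_psd()] result (or any `power_spectrum`).
#' @param cfg a [spectral_config()].
#' @return Object of class `spectral_model`: `aperiodic` (named vector
#'   `offset`, `knee`, `exponent`), `knee_freq_hz`, `peaks` (data frame
#'   `center_freq_hz`, `power`, `bandwidth_hz`), goodness of fit
#'   (`r_squared`, `mae`, computed over the fit range in log10 space),
#'   the fitted curves, and a `converged` flag. On non-convergence the
#'   parameters are `NaN` and `converged` is `FALSE`.
#' @export
fit_spectral_model <- function(psd, cfg = spectral_config()) {
  stopifnot(inherits(psd, "power_spectrum"))
  sel <- psd$freqs_hz >= cfg$fit_range_hz[1] &
    psd$freqs_hz <= cfg$fit_range_hz[2]
  f <- psd$freqs_hz[sel]
  p <- psd$power[sel]
  if (length(f) < 5) stop("fewer than 5 frequency bins in the fit range")
  if (any(p <= 0)) stop("power must be positive over the fit range")
  y <- log10(p)
  mode <- cfg$aperiodic_mode
  failed <- structure(
    list(aperiodic = c(offset = NaN, knee = NaN, exponent = NaN),
         knee_freq_hz = NaN,
         peaks = data.frame(center_freq_hz = numeric(), power = numeric(),
                            bandwidth_hz = numeric()),
         r_squared = NaN, mae = NaN, freqs_hz = f, log_power = y,
         model_log10 = rep(NaN, length(f)),
         aperiodic_log10 = rep(NaN, length(f)),
         fit_range_hz = cfg$fit_range_hz, mode = mode,
         converged = FALSE, source = psd$source),
    class = "spectral_model")
  res <- tryCatch({
    ap0 <- fit_aperiodic(f, y, mode)
    apr <- robust_aperiodic(f, y, mode, ap0)
    ap_curve <- aperiodic_curve(f, apr$params[1], apr$params[2],
                                apr$params[3], mode)
    flat <- y - ap_curve
    w_lo <- cfg$peak_width_limits_hz[1] / 2
    w_hi <- cfg$peak_width_limits_hz[2] / 2
    guesses <- list()
    work <- flat
    for (i in seq_len(cfg$max_n_peaks)) {
      imax <- which.max(work)
      h <- work[imax]
      if (h <= cfg$peak_threshold_sd * sd(work)) break
      cf <- f[imax]
      half <- h / 2
      li <- imax; while (li > 1L && work[li] > half) li <- li - 1L
      ri <- imax; while (ri < length(f) && work[ri] > half) ri <- ri + 1L
      sd_g <- min(w_hi, max(w_lo, (f[ri] - f[li]) / 2.355))
      # drop guesses hugging the fit-range edge; still subtract them so
      # the search can move on
      if (cf - f[1] >= sd_g && f[length(f)] - cf >= sd_g)
        guesses[[length(guesses) + 1L]] <- c(cf, h, sd_g)
      work <- work - gaussian_curve(f, cf, h, sd_g)
    }
    peaks <- matrix(numeric(0), ncol = 3)
    if (length(guesses) > 0) {
      g0 <- do.call(rbind, guesses)
      npk <- nrow(g0)
      obj <- function(th) {
        m <- matrix(th, ncol = 3)
        pred <- 0
        for (j in seq_len(npk))
          pred <- pred + gaussian_curve(f, m[j, 1], m[j, 2], m[j, 3])
        r <- flat - pred
        sum(r * r)
      }
      lower <- c(pmax(f[1], g0[, 1] - 2 * g0[, 3]), rep(0, npk),
                 rep(w_lo, npk))
      upper <- c(pmin(f[length(f)], g0[, 1] + 2 * g0[, 3]),
                 rep(2 * max(flat), npk), rep(w_hi, npk))
      fitp <- nlminb(as.numeric(g0), obj, lower = lower, upper = upper,
                     control = list(iter.max = 1000))
      peaks <- matrix(fitp$par, ncol = 3)
      # prune vanished and overlapping peaks (keep the taller)
      peaks <- peaks[peaks[, 2] > 1e-4, , drop = FALSE]
      if (nrow(peaks) > 1) {
        ord <- order(-peaks[, 2])
        keep <- rep(TRUE, nrow(peaks))
        for (a in seq_along(ord)) for (b in seq_along(ord)) {
          if (a >= b || !keep[ord[a]] || !keep[ord[b]]) next
          if (abs(peaks[ord[a], 1] - peaks[ord[b], 1]) <
              0.75 * max(peaks[ord[a], 3], peaks[ord[b], 3]))
            keep[ord[b]] <- FALSE
        }
        peaks <- peaks[keep, , drop = FALSE]
      }
    }
    peak_curve <- 0
    if (nrow(peaks) > 0)
      for (j in seq_len(nrow(peaks)))
        peak_curve <- peak_curve +
          gaussian_curve(f, peaks[j, 1], peaks[j, 2], peaks[j, 3])
    ap_final <- fit_aperiodic(f, y - peak_curve, mode, init = apr$params)
    ap <- ap_final$params
    ap_log <- aperiodic_curve(f, ap[1], ap[2], ap[3], mode)
    model <- ap_log + peak_curve
    fk <- if (mode == "knee") unname(ap[2])^(1 / unname(ap[3])) else NaN
    out <- failed
    out$aperiodic <- ap
    out$knee_freq_hz <- fk
    out$peaks <- data.frame(center_freq_hz = peaks[, 1],
                            power = peaks[, 2],
                            bandwidth_hz = 2 * peaks[, 3])
    out$r_squared <- if (var(y) > 0) 1 - sum((y - model)^2) / sum((y - mean(y))^2) else NaN
    out$mae <- mean(abs(y - model))
    out$model_log10 <- model
    out$aperiodic_log10 <- ap_log
    out$converged <- TRUE
    out
  }, error = function(e) {
    warning("spectral model fit failed: ", conditionMessage(e))
    failed
  })
  res
}

#' @export
print.spectral_model <- function(x, ...) {
  if (!x$converged) {
    cat("spectral_model: fit did not converge (parameters NaN)\n")
    return(invisible(x))
  }
  cat(sprintf(
    paste0("spectral_model (%s mode): offset %.3f, knee %.3g, exponent %.3f",
           " -> knee freq %.3g Hz (tau %.3g ms)\n"),
    x$mode, x$aperiodic[1], x$aperiodic[2], x$aperiodic[3],
    x$knee_freq_hz, tau_from_knee(x)))
  cat(sprintf("  %d peak(s); R^2 = %.4f, MAE = %.4f (log10 power)\n",
              nrow(x$peaks), x$r_squared, x$mae))
  invisible(x)
}

#' Timescale from the aperiodic knee
#'
#' Converts knee parameters to a timescale: the knee frequency is
#' `f_k = knee^(1/exponent)` and `tau = 1/(2*pi*f_k)`, returned in
#' milliseconds.
#'
#' @param x a `spectral_model`, or a named vector/list with `knee` and
#'   `exponent`.
#' @return Timescale in ms (`NaN`, with a warning, if knee or exponent is
#'   not positive).
#' @export
tau_from_knee <- function(x) {
  if (inherits(x, "spectral_model")) x <- as.list(x$aperiodic)
  x <- as.list(x)
  k <- as.numeric(x$knee); chi <- as.numeric(x$exponent)
  if (!is.finite(k) || !is.finite(chi) || k <= 0 || chi <= 0) {
    warning("undefined timescale: knee and exponent must be positive")
    return(NaN)
  }
  fk <- k^(1 / chi)
  1000 / (2 * pi * fk)
}

#' Total oscillatory power of a fitted spectral model
#'
#' Sum of the (log10-power) heights of all periodic peaks; 0 when the
#' spectrum is purely aperiodic.
#'
#' @param model a `spectral_model`.
#' @return Scalar total oscillatory power.
#' @export
total_oscillatory_power <- function(model) {
  stopifnot(inherits(model, "spectral_model"))
  if (nrow(model$peaks) == 0L) 0 else sum(model$peaks$power)
}

#' Construct a model power spectrum (generator for tests and examples)
#'
#' Evaluates the generalized Lorentzian plus optional Gaussian peaks on a
#' frequency grid and returns a `power_spectrum` in linear power. Useful
#' as an exact-oracle input for [fit_spectral_model()].
#'
#' @param freqs_hz frequency grid (> 0).
#' @param offset,knee,exponent aperiodic parameters.
#' @param peaks optional data frame with `center_freq_hz`, `power`,
#'   `bandwidth_hz`.
#' @return A `power_spectrum`.
#' @export
model_psd <- function(freqs_hz, offset, knee, exponent, peaks = NULL) {
  y <- aperiodic_curve(freqs_hz, offset, knee, exponent, "knee")
  if (!is.null(peaks) && nrow(peaks) > 0)
    for (j in seq_len(nrow(peaks)))
      y <- y + gaussian_curve(freqs_hz, peaks$center_freq_hz[j],
                              peaks$power[j], peaks$bandwidth_hz[j] / 2)
  structure(list(freqs_hz = freqs_hz, power = 10^y, fs_hz = NA,
                 n_segments = 1L, source = "model"),
            class = "power_spectrum")
}

#' One-call spectral timescale estimate
#'
#' Computes the Welch PSD of a signal and fits the spectral model,
#' returning the knee-derived timescale.
#'
#' @param x numeric signal.
#' @param fs_hz sampling rate, Hz.
#' @param cfg a [spectral_config()].
#' @return List: `tau_ms`, `knee_freq_hz`, `model`.
#' @export
estimate_tau_spectral <- function(x, fs_hz, cfg = spectral_config()) {
  model <- fit_spectral_model(welch_psd(x, fs_hz, cfg), cfg)
  tau <- if (model$converged) suppressWarnings(tau_from_knee(model)) else NaN
  list(tau_ms = tau, knee_freq_hz = model$knee_freq_hz, model = model)
}
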