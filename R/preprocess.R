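#' Raw extracellular recording container
#'
#' @param traces numeric matrix of voltage samples, channels x samples
#'   (microvolts).
#' @param fs_hz sampling rate, Hz (MEA recordings of the kind this path
#'   targets are sampled at 12,500 Hz).
#' @param channel_ids optional channel identifiers.
#' @param well_id optional well label.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(traces, fs_hz, channel_ids = NULL, well_id = NA) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1L)
  traces <- as.matrix(traces)
  if (!is.numeric(traces)) stop("'traces' must be numeric")
  if (fs_hz <= 0) stop("'fs_hz' must be positive")
  if (is.null(channel_ids)) channel_ids <- as.character(seq_len(nrow(traces)))
  if (length(channel_ids) != nrow(traces))
    stop("'channel_ids' must have one entry per channel")
  structure(list(traces = traces, fs_hz = fs_hz,
                 channel_ids = as.character(channel_ids), well_id = well_id),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d channel(s) x %d samples at %g Hz (well %s)\n",
              nrow(x$traces), ncol(x$traces), x$fs_hz, x$well_id))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Defaults follow the organoid MEA pipeline: median referencing across
#' channels, third-order Butterworth band-pass from 300 to 3,000 Hz,
#' spike threshold at 5.5 robust standard deviations, 1-ms enforced delay
#' between spikes, network events at half the maximal population activity
#' with windows from 0.5 s before to 2.5 s after onset, and 100-ms bins
#' for the autocorrelation path.
#'
#' @param band_lo_hz,band_hi_hz band-pass edges, Hz.
#' @param filter_order Butterworth order.
#' @param threshold_multiplier spike threshold in units of the robust SD
#'   estimate `median(|x|) / 0.6745`.
#' @param refractory_ms enforced minimum delay between detected spikes, ms.
#' @param event_threshold_frac network-event threshold as a fraction of the
#'   maximal population activity (in `(0, 1]`).
#' @param event_pre_s,event_post_s window extent before/after event onset, s.
#' @param bin_width_ms spike-count bin width for the ACF path, ms.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(band_lo_hz = 300, band_hi_hz = 3000,
                              filter_order = 3, threshold_multiplier = 5.5,
                              refractory_ms = 1, event_threshold_frac = 0.5,
                              event_pre_s = 0.5, event_post_s = 2.5,
                              bin_width_ms = 100) {
  if (!(band_lo_hz > 0 && band_lo_hz < band_hi_hz))
    stop("need 0 < band_lo_hz < band_hi_hz")
  if (threshold_multiplier <= 0) stop("'threshold_multiplier' must be > 0")
  if (!(event_threshold_frac > 0 && event_threshold_frac <= 1))
    stop("'event_threshold_frac' must be in (0, 1]")
  if (refractory_ms <= 0) stop("'refractory_ms' must be > 0")
  if (bin_width_ms <= 0) stop("'bin_width_ms' must be > 0")
  structure(list(band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
                 filter_order = filter_order,
                 threshold_multiplier = threshold_multiplier,
                 refractory_ms = refractory_ms,
                 event_threshold_frac = event_threshold_frac,
                 event_pre_s = event_pre_s, event_post_s = event_post_s,
                 bin_width_ms = bin_width_ms),
            class = "preprocess_config")
}

#' Median-reference and band-pass filter a raw recording
#'
#' Subtracts the per-sample median across channels (common-mode reference;
#' needs at least 2 channels), then applies a zero-phase Butterworth
#' band-pass per channel. Zero-phase (forward-backward) filtering is used
#' so spike timing is not shifted.
#'
#' @param rec a [raw_recording()].
#' @param cfg a [preprocess_config()].
#' @return A [raw_recording()] with referenced, filtered traces.
#' @export
reference_and_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  if (nrow(rec$traces) < 2)
    stop("median referencing needs at least 2 channels")
  if (cfg$band_hi_hz >= rec$fs_hz / 2)
    stop("'band_hi_hz' must be below the Nyquist frequency")
  ref <- apply(rec$traces, 2, median)
  traces <- sweep(rec$traces, 2, ref)
  flt <- butter_bandpass(cfg$filter_order, cfg$band_lo_hz, cfg$band_hi_hz,
                         rec$fs_hz)
  for (i in seq_len(nrow(traces)))
    traces[i, ] <- filtfilt_zero_phase(flt$b, flt$a, traces[i, ])
  raw_recording(traces, rec$fs_hz, rec$channel_ids, rec$well_id)
}

#' Detect spikes by adaptive amplitude threshold
#'
#' Per channel, the threshold is `threshold_multiplier` times the robust
#' noise estimate `median(|x|) / 0.6745`. A spike is registered at the peak
#' of `|x|` within one refractory period after an upward threshold
#' crossing, and successive spikes are at least `refractory_ms` apart.
#'
#' @param rec a (filtered) [raw_recording()].
#' @param cfg a [preprocess_config()].
#' @return Spike table: data frame with `unit_id` (channel id) and `time_s`.
#' @export
detect_spikes <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  ref_n <- max(1L, round(cfg$refractory_ms / 1000 * rec$fs_hz))
  out <- lapply(seq_len(nrow(rec$traces)), function(ci) {
    x <- abs(rec$traces[ci, ])
    sigma <- median(x) / 0.6745
    if (sigma == 0) return(NULL)             # flat channel: zero spikes
    thr <- cfg$threshold_multiplier * sigma
    n <- length(x)
    above <- x > thr
    if (!any(above)) return(NULL)
    crossings <- which(above & !c(FALSE, above[-n]))
    times <- integer(0)
    last <- -Inf
    for (cr in crossings) {
      if (cr - last < ref_n) next
      win <- cr:min(n, cr + ref_n - 1L)
      pk <- win[which.max(x[win])]
      if (pk - last < ref_n) next            # refractory merge
      times <- c(times, pk)
      last <- pk
    }
    if (length(times) == 0L) return(NULL)
    data.frame(unit_id = rec$channel_ids[ci], time_s = (times - 1L) / rec$fs_hz)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(unit_id = character(), time_s = numeric())
  out
}

#' Detect network events in a population spiking vector
#'
#' Network events are bursts in which population activity exceeds
#' `event_threshold_frac` of the maximal activity in the recording. The
#' onset is the left edge of the first suprathreshold bin of a run; the
#' event window runs from `event_pre_s` before to `event_post_s` after
#' onset, clipped to the recording bounds. Suprathreshold runs whose onset
#' falls inside a previous window are merged into it.
#'
#' @param pop a single-row [spike_raster()] (see [population_vector()]) or
#'   numeric vector; if a vector, `bin_width_s` and `t0_s` must be given.
#' @param cfg a [preprocess_config()].
#' @param bin_width_s,t0_s binning metadata when `pop` is a bare vector.
#' @return Data frame of event windows: `onset_s`, `start_s`, `end_s`.
#' @export
detect_network_events <- function(pop, cfg = preprocess_config(),
                                  bin_width_s = NULL, t0_s = 0) {
  if (inherits(pop, "spike_raster")) {
    v <- colSums(pop$counts)
    bin_width_s <- pop$bin_width_s
    t0_s <- pop$t0_s
  } else {
    v <- as.numeric(pop)
    if (is.null(bin_width_s)) stop("'bin_width_s' required for a bare vector")
  }
  if (length(v) == 0L) stop("empty population vector")
  empty <- data.frame(onset_s = numeric(), start_s = numeric(),
                      end_s = numeric())
  if (max(v) == 0) return(empty)
  thr <- cfg$event_threshold_frac * max(v)
  above <- v > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  run_start <- cumsum(c(1L, head(r$lengths, -1L)))[r$values]
  t_end <- t0_s + length(v) * bin_width_s
  events <- empty
  for (b in run_start) {
    onset <- t0_s + (b - 1L) * bin_width_s
    if (nrow(events) > 0 && onset < events$end_s[nrow(events)])
      next                                    # merged into previous window
    events <- rbind(events, data.frame(
      onset_s = onset,
      start_s = max(t0_s, onset - cfg$event_pre_s),
      end_s = min(t_end, onset + cfg$event_post_s)))
  }
  events
}

#' Extract per-channel raster segments for event windows
#'
#' Slices the raster to each event window. Windows extending beyond the
#' recording are clipped (with a warning). Segment lengths equal the
#' (clipped) window durations in bins.
#'
#' @param raster a [spike_raster()].
#' @param windows data frame from [detect_network_events()].
#' @return List with one element per event: list of `counts`
#'   (channels x bins matrix), `start_s`, `end_s`, `onset_s`.
#' @export
extract_event_data <- function(raster, windows) {
  stopifnot(inherits(raster, "spike_raster"))
  n_bins <- ncol(raster$counts)
  t_end <- raster$t0_s + n_bins * raster$bin_width_s
  lapply(seq_len(nrow(windows)), function(i) {
    s <- windows$start_s[i]; e <- windows$end_s[i]
    if (s < raster$t0_s - 1e-9 || e > t_end + 1e-9) {
      warning(sprintf("event window [%g, %g] clipped to recording bounds",
                      s, e))
      s <- max(s, raster$t0_s); e <- min(e, t_end)
    }
    i0 <- round((s - raster$t0_s) / raster$bin_width_s) + 1L
    len <- round((e - s) / raster$bin_width_s)
    i1 <- min(n_bins, i0 + len - 1L)
    list(counts = raster$counts[, i0:i1, drop = FALSE],
         start_s = s, end_s = e, onset_s = windows$onset_s[i])
  })
}
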