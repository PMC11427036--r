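---
title: "Estimating neuronal timescales from spiking activity: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating neuronal timescales from spiking activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiketau)
```

## The problem

The intrinsic neuronal timescale $\tau$ is the characteristic duration over
which the activity of a neural population remains correlated with itself.
`spiketau` estimates $\tau$ from spiking data by two routes, and then asks
how $\tau$ changes across a developmental series of recordings:

1. **ACF method** (the traditional route): fit $A e^{-t/\tau} + c$ to the
   autocorrelation function of binned spike counts.
2. **Spectral parameterization**: decompose the log-power spectrum into an
   aperiodic component plus narrowband peaks, and read the timescale off
   the *knee frequency* of the aperiodic component.

The spectral route exists because the ACF route is biased whenever
oscillations ride on top of the aperiodic dynamics: a rhythmic component
adds a cosine to the ACF that the exponential fit cannot separate from the
decay. The spectral model isolates oscillatory power into explicit peak
terms, leaving the aperiodic knee — and hence $\tau$ — unbiased.

## The aperiodic model

In log10 power the aperiodic component is a generalized Lorentzian,

$$L(f) = b - \log_{10}\!\left(k + f^{\chi}\right),$$

with offset $b$, knee parameter $k$ and exponent $\chi$. The knee frequency
is $f_k = k^{1/\chi}$ — the frequency where the spectrum bends from flat to
a power-law decay of slope $-\chi$ — and the timescale is

$$\tau = \frac{1}{2\pi f_k},$$

reported in milliseconds. Narrowband (periodic) components are Gaussians in
log10 power over frequency; the sum of their heights is the *total
oscillatory power*. For an Ornstein–Uhlenbeck-like (shot-noise) process
with correlation time $\tau$ the spectrum is exactly Lorentzian
($\chi = 2$, $f_k = 1/2\pi\tau$), which provides the closed-form oracle
used throughout the test suite.

### Fitting algorithm

`fit_spectral_model()` is iterative, in the style of standard
spectral-parameterization toolboxes:

1. least-squares fit of $L(f)$ to the log10 spectrum over the fit range
   (multi-start over knee/exponent initializations, box-constrained);
2. *robust refit*: points lying clearly above the first curve (putative
   peaks) are dropped and the aperiodic curve is refit on the lower
   envelope;
3. peak detection on the flattened spectrum: the largest residual maximum
   is accepted while it exceeds `peak_threshold_sd` standard deviations of
   the flattened spectrum, seeded with a half-height width estimate, up to
   `max_n_peaks` peaks; guesses hugging the fit-range edge are discarded;
4. joint refit of all Gaussians, pruning vanished and overlapping peaks
   (centers closer than 0.75 of the wider SD keep only the taller peak);
5. final aperiodic fit on the peak-subtracted spectrum, and goodness of
   fit ($R^2$ and mean absolute error in log10 power) over the fit range.

Convergence failures return a flagged model with `NaN` parameters rather
than an error, so that batch pipelines can log and exclude them.

### Parameters that matter

| parameter | default | why |
|---|---|---|
| `welch_window_s` / `welch_overlap_s` | 1.0 s Hamming / 0.5 s | the standard spiking-PSD recipe; 1-Hz resolution |
| `fit_range_hz` | 0.5–100 Hz | upper bound matches the 100-Hz knee-frequency outlier cut; no published range exists, so this is an implementation choice |
| `max_n_peaks` | 6 | enough for multi-band activity without chasing noise |
| `peak_threshold_sd` | 2.0 | relative threshold on the flattened spectrum |
| `peak_width_limits_hz` | 0.5–12 Hz | bandwidth = 2 SD; lower limit near the frequency resolution |
| `aperiodic_mode` | `"knee"` | the knee is the quantity of interest; `"fixed"` exists for diagnostics |

## The ACF method

`compute_acf()` produces the normalized autocorrelation at integer-bin
lags (100-ms bins with lags to 3,000 ms for culture-style population
vectors; simulated traces use their native 1-ms binning).
`fit_exp_decay()` fits $A e^{-t/\tau} + c$ by profiling $\tau$: for fixed
$\tau$ the amplitude and offset are linear, so the search is a 1-D
bounded optimization ($\tau \in [1\,\mathrm{ms}, 10\,\mathrm{s}]$, log
grid then local refinement). Lag 0 is excluded: the zero-lag spike-count
variance of a point process sits above the exponential's intercept. The
free $A$ and $c$ absorb that and the finite-duration ACF baseline; the
bare $e^{-t/\tau}$ fit is available via `fit_amplitude`/`fit_offset` for
comparison.

## The simulator and what it does (and does not) emulate

`simulate_timescale_train()` draws a homogeneous Poisson population
impulse train (pooled rate `input_rate_hz`), convolves it with the
exponential synaptic kernel $e^{-t/\tau}$ (sampled at `fs_hz`, truncated
at $10\tau$, peak-normalized), rescales the result to a per-sample spiking
probability with mean `base_rate_hz / fs_hz`, optionally adds a sine
modulation, and Bernoulli-samples spike trains from that probability.

Numerical choices:

* **Rescaling happens after clipping.** The probability trace is clipped
  to $[0,1]$; the scale is found by bisection so the *post-clip* mean hits
  the target rate exactly. With the default smooth-latent regime clipping
  never engages, but sparse-input configurations would otherwise
  under-deliver spikes.
* **Oscillations are additive by default** (amplitude
  `osc_strength * mean(p)`), with a multiplicative mode available. The
  modulation frequency must be below Nyquist.
* **`input_rate_hz = 2000`** (1,000 presynaptic neurons at 2 Hz): the
  latent trace is then smooth, so an added oscillation of strength 0.5
  dominates the latent fluctuations — the regime in which the ACF bias is
  visible and the spectral method earns its keep.

### Which signal should the estimators see?

A binary spike train carries, besides the latent Lorentzian dynamics, a
flat Poisson counting-noise floor at a spectral density of order
$\bar r / f_s^2$ (in probability units). For a 20-Hz train this floor sits
roughly one decade below the Lorentzian plateau, which buries the knee of
slow timescales (for $\tau = 50$ ms, $f_k \approx 3.2$ Hz, the floor
dominates the fit range above roughly 10–30 Hz at any Poisson input
rate). Short timescales (5–10 ms) remain recoverable from rasters; slow
ones are not, at realistic rates and durations — this is an information
limit of the point process, not a fitting defect. The simulation
validation experiments therefore parameterize the **latent
synaptic-activity trace** (returned alongside the raster), exactly as the
reference simulation practice does for aperiodic field-potential
backgrounds; the raster path remains available (`signal = "spikes"` in
the pipeline) and is exercised for fast timescales in the tests.

`simulate_mea_recording()` adds MEA-like structure: channels share planted
burst epochs (elevated common rate) between near-silent gaps, so half-max
network-event detection has a ground-truth onset list to be checked
against. `simulate_study()` wraps either simulator into a multi-timepoint
"developmental study" whose ground-truth $\tau(t)$ follows a constant,
sigmoid or Gaussian trajectory with per-channel jitter, and emits the
truth table used for recovery tests.

What the generator does *not* emulate: refractoriness, bursting
statistics of real single units, nonstationary rates within a recording,
electrode noise and artifact structure, or correlated per-channel kernel
heterogeneity. A green test on synthetic data therefore establishes that
the estimation chain is correct for the stated generative model — not
that real recordings satisfy that model.

## Preprocessing path (MEA rasters from raw voltage)

`reference_and_filter()` subtracts the per-sample median across channels
and applies a zero-phase third-order Butterworth band-pass (300–3,000 Hz
defaults). Filtering is forward–backward so spike times are not shifted;
the filter design (analog prototype, LP→BP transform, bilinear transform)
is implemented in the package and validated against analytic
frequency-response oracles because no DSP dependency is available.
`detect_spikes()` thresholds $|x|$ at 5.5 robust standard deviations
($\hat\sigma = \mathrm{median}(|x|)/0.6745$), places the spike at the peak
within 1 ms of the crossing, and enforces a 1-ms delay between spikes.
`detect_network_events()` thresholds the population vector at half its
maximum; windows run from 0.5 s before onset to 2.5 s after, clipped at
recording bounds, with runs starting inside a previous window merged into
it (a rule chosen to avoid duplicated spectra from overlapping windows —
the alternative, extension, would violate the fixed window length).
Bins are half-open $[a, b)$; onsets are the left edge of the first
suprathreshold bin.

For power spectra inside 3-s event windows the raster is kept at 1-ms
bins: 100-ms binning would cap observable knee frequencies at 5 Hz,
inconsistent with a 100-Hz knee-frequency outlier bound. The ACF path
keeps the canonical 100-ms bins. Both are configurable.

## Trajectory statistics

Per-channel estimates pass an outlier ladder
(`filter_outliers()`): MEA style — knee frequency outside
$[0.01, 100]$ Hz removed, then a per-timepoint $\pm 4$ SD cut on log10
timescales (skipped, and logged, where fewer than 3 values survive);
single-unit culture style — timescales over 100 ms removed, then
averaging across units within a culture. Every stage logs in/out counts,
and input = kept + removed is asserted as a test invariant.

`fit_trajectory()` fits the per-timepoint means (the published choice;
fitting all points is possible by passing the unaggregated table) with
three families: constant (exactly the sample mean), 4-parameter logistic
sigmoid, and Gaussian-plus-offset. Comparisons use `f_test()`: nested
models get the extra-sum-of-squares F with
$\mathrm{df} = (p_2 - p_1,\; n - p_2)$; the sigmoid-vs-Gaussian
comparison has zero numerator df as a nested test, so it is reported as a
two-sided variance-ratio F instead. All tests are two-sided and
uncorrected.

One identifiability constraint deserves note: the Gaussian width is
bounded below by the median timepoint spacing (and the sigmoid transition
scale by a quarter of it). A trajectory feature narrower than the
sampling interval is indistinguishable from noise at a single timepoint,
and permitting it lets the 4-parameter families chase single-point noise,
inflating the false-positive rate of the nested F test well above its
nominal level under a constant truth.

`postnatal_day()` converts days in vitro to postnatal-equivalence days,
$\mathrm{divs} - (\mathrm{gestation} - \mathrm{extraction\ day})$, i.e.
$\mathrm{divs} - 5$ with the rat defaults (in vitro day 6 is postnatal
day 1). `compare_endpoints()` is the pooled-variance two-sample t test
used to contrast timescale distributions at two timepoints.

## Worked example

```{r example, eval = FALSE}
# simulate a developmental study whose true timescale follows a Gaussian
cfg <- trajectory_study_config(
  timepoints = seq(100, 350, length.out = 8),
  family = "gaussian",
  family_params = list(a = 30, mu = 250, sigma = 60, c = 10),
  channels_per_timepoint = 8,
  sim_template = sim_config(tau_ms = 10, duration_s = 30,
                            base_rate_hz = 20),
  noise_sd_ms = 3, seed = 1)

report <- run_pipeline(pipeline_config(study = cfg, seed = 1))
report$selected_model          # "gaussian"
report$comparisons[["gaussian vs constant"]]
```

## Known limitations

* Slow timescales cannot be read off binary spike rasters of realistic
  rate/duration through the spectral route (counting-noise floor, above);
  use population sums, longer recordings, or the latent-trace path.
* The nested F test on nonlinear fits is approximate; its false-positive
  rate is validated by simulation at the defaults but not guaranteed for
  other designs.
* The equal-complexity variance-ratio comparison is a pragmatic
  substitute for a test the literature leaves unspecified.
* No HDF5 I/O: rasters and spike tables are exchanged as delimited text
  with JSON sidecars.
* Estimation assumes stationarity within a recording (or within event
  windows); drifting rates bias both routes.
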