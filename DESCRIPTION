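Package: spiketau
Title: Neuronal Timescale Estimation from Spiking Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates intrinsic neuronal timescales from spiking data by two
    routes: exponential-decay fitting of spike-count autocorrelation
    functions, and aperiodic ("knee") parameterization of Welch power
    spectra, in which the log-power spectrum is decomposed into a
    generalized Lorentzian aperiodic component plus narrowband Gaussian
    peaks and the timescale is recovered from the knee frequency as
    tau = 1/(2*pi*f_k). Includes a multielectrode-array preprocessing path
    (median referencing, Butterworth band-pass filtering, adaptive-threshold
    spike detection, network-event extraction), developmental-trajectory
    model comparison (constant, sigmoid and Gaussian fits with pairwise
    F tests), and a spike-train simulator with known ground-truth
    timescales for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
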