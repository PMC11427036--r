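# Butterworth band-pass design and zero-phase filtering.
# Hand-written (no DSP package in the dependency stack): analog prototype
# poles -> low-pass-to-band-pass transform -> bilinear transform, following
# the standard derivation, with the recursive filter pass in C++.

poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
  cf
}

#' Butterworth band-pass filter coefficients
#'
#' Designs a digital Butterworth band-pass filter (order `order` per edge,
#' so `2 * order` poles) via the bilinear transform with frequency
#' prewarping.
#'
#' @param order filter order (per band edge); 3 is the preprocessing
#'   default.
#' @param lo_hz,hi_hz band edges in Hz; must satisfy
#'   `0 < lo_hz < hi_hz < fs_hz / 2`.
#' @param fs_hz sampling rate in Hz.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(order, lo_hz, hi_hz, fs_hz) {
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < fs_hz / 2))
    stop("band edges must satisfy 0 < lo_hz < hi_hz < fs_hz/2")
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  p_lp <- complex(real = -sin(theta), imaginary = cos(theta))
  # prewarp edges, transform low-pass prototype to band-pass
  fs2 <- 2 * fs_hz
  w1 <- fs2 * tan(pi * lo_hz / fs_hz)
  w2 <- fs2 * tan(pi * hi_hz / fs_hz)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  p_bp <- unlist(lapply(p_lp, function(p) {
    d <- sqrt((p * bw)^2 / 4 - w0^2 + 0i)
    c(p * bw / 2 + d, p * bw / 2 - d)
  }))
  # bilinear transform; band-pass has `order` zeros at s = 0 and `order`
  # at infinity, mapping to z = 1 and z = -1
  z_dig <- c(rep(1 + 0i, order), rep(-1 + 0i, order))
  p_dig <- (fs2 + p_bp) / (fs2 - p_bp)
  b <- poly_from_roots(z_dig)
  a <- poly_from_roots(p_dig)
  # normalize gain to 1 at the (warped) center frequency
  wc <- 2 * atan(w0 / fs2)
  zc <- exp(1i * wc)
  h <- sum(b * zc^-(seq_along(b) - 1)) / sum(a * zc^-(seq_along(a) - 1))
  list(b = Re(b) / Mod(h), a = Re(a))
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward and backward so the net phase response is
#' zero and spike timing is preserved; the effective magnitude response is
#' the square of the single-pass response. Edges are handled by
#' odd-reflection padding.
#'
#' @param b,a filter coefficients, e.g. from [butter_bandpass()].
#' @param x numeric signal.
#' @return Filtered signal of the same length.
#' @export
filtfilt_zero_phase <- function(b, a, x) {
  n <- length(x)
  padlen <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 4L)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    ext <- c(pre, x, post)
  } else ext <- x
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}
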