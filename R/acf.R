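#' Autocorrelation function of binned spiking
#'
#' Normalized autocorrelation at integer-bin lags up to `max_lag_s`
#' (`acf(0) = 1`). This is the input to the traditional timescale
#' estimator, [fit_exp_decay()]. The canonical spiking recipe uses 100-ms
#' bins with lags out to 3,000 ms; simulated traces at finer binning use
#' their own bin width.
#'
#' @param x numeric vector of binned counts (or a single-row
#'   [spike_raster()]).
#' @param bin_width_s bin width of `x` in seconds (taken from the raster
#'   if one is supplied).
#' @param max_lag_s maximum lag, seconds; the recording must be at least
#'   twice this long.
#' @return Object of class `acf_fun`: `lags_s`, `acf` (values in
#'   `[-1, 1]`), `bin_width_s`, `ok` (`FALSE`, with `NaN` values, for
#'   zero-variance input).
#' @export
compute_acf <- function(x, bin_width_s = NULL, max_lag_s = 3.0) {
  if (inherits(x, "spike_raster")) {
    if (nrow(x$counts) != 1L)
      stop("supply a single-row raster (see population_vector())")
    bin_width_s <- x$bin_width_s
    x <- as.numeric(x$counts[1L, ])
  }
  x <- as.numeric(x)
  if (is.null(bin_width_s) || bin_width_s <= 0)
    stop("'bin_width_s' must be a positive number")
  n_lag <- floor(max_lag_s / bin_width_s + 1e-9)
  if (length(x) < 2 * n_lag)
    stop("need at least 2 * max_lag_s of data")
  lags_s <- (0:n_lag) * bin_width_s
  if (var(x) == 0) {
    warning("zero-variance input: autocorrelation undefined")
    return(structure(list(lags_s = lags_s,
                          acf = c(1, rep(NaN, n_lag)),
                          bin_width_s = bin_width_s, ok = FALSE),
                     class = "acf_fun"))
  }
  vals <- as.numeric(acf(x, lag.max = n_lag, plot = FALSE, demean = TRUE,
                         type = "correlation")$acf)
  structure(list(lags_s = lags_s, acf = vals, bin_width_s = bin_width_s,
                 ok = TRUE),
            class = "acf_fun")
}

#' @export
print.acf_fun <- function(x, ...) {
  cat(sprintf("acf_fun: %d lags at %g s bins, max lag %g s%s\n",
              length(x$lags_s), x$bin_width_s, max(x$lags_s),
              if (x$ok) "" else " (flagged: zero variance)"))
  invisible(x)
}

#' Timescale from exponential decay of the autocorrelation
#'
#' Least-squares fit of `A * exp(-t / tau) + c` to the autocorrelation at
#' positive lags. Lag 0 is excluded because the zero-lag spike-count
#' variance of a point process inflates `acf(0)` above the exponential's
#' intercept; the free amplitude and offset absorb that and the finite
#' -duration baseline. For a fixed `tau` the amplitude and offset are
#' linear, so the fit profiles `tau` over a bounded log grid
#' (`tau` in `[1 ms, 10 s]`) and refines the best candidate, which makes
#' the exact-inverse property hold to numerical precision on analytic
#' exponential ACFs.
#'
#' @param af an [compute_acf()] result.
#' @param fit_amplitude,fit_offset include the amplitude / offset terms;
#'   disabling both fits the bare `exp(-t/tau)`.
#' @param tau_bounds_ms search bounds for `tau`, ms.
#' @return Object of class `exp_decay_fit`: `tau_ms`, `amplitude`,
#'   `offset`, `rss`, `converged` (`FALSE` when the optimum sticks to a
#'   search bound or the input was flagged).
#' @export
fit_exp_decay <- function(af, fit_amplitude = TRUE, fit_offset = TRUE,
                          tau_bounds_ms = c(1, 10000)) {
  stopifnot(inherits(af, "acf_fun"))
  sel <- af$lags_s > 0
  t_s <- af$lags_s[sel]
  y <- af$acf[sel]
  if (length(t_s) < 4) stop("need at least 4 positive-lag points")
  if (!af$ok || any(!is.finite(y)))
    return(structure(list(tau_ms = NaN, amplitude = NaN, offset = NaN,
                          rss = NaN, converged = FALSE),
                     class = "exp_decay_fit"))
  rss_tau <- function(tau_s) {
    e <- exp(-t_s / tau_s)
    if (fit_amplitude && fit_offset) {
      X <- cbind(e, 1)
      cf <- tryCatch(qr.coef(qr(X), y), error = function(err) c(NA, NA))
      if (any(!is.finite(cf))) return(list(rss = Inf, A = NaN, c = NaN))
      r <- y - X %*% cf
      list(rss = sum(r * r), A = cf[1], c = cf[2])
    } else if (fit_amplitude) {
      A <- sum(e * y) / sum(e * e)
      r <- y - A * e
      list(rss = sum(r * r), A = A, c = 0)
    } else {
      r <- y - e
      list(rss = sum(r * r), A = 1, c = 0)
    }
  }
  lo <- tau_bounds_ms[1] / 1000; hi <- tau_bounds_ms[2] / 1000
  grid <- exp(seq(log(lo), log(hi), length.out = 200))
  rss_g <- vapply(grid, function(g) rss_tau(g)$rss, numeric(1))
  i <- which.min(rss_g)
  bracket <- c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)])
  opt <- optimize(function(g) rss_tau(g)$rss, interval = bracket,
                  tol = .Machine$double.eps^0.5)
  best <- rss_tau(opt$minimum)
  tau_ms <- opt$minimum * 1000
  at_bound <- tau_ms <= tau_bounds_ms[1] * 1.001 ||
    tau_ms >= tau_bounds_ms[2] * 0.999
  structure(list(tau_ms = tau_ms, amplitude = unname(best$A),
                 offset = unname(best$c), rss = best$rss,
                 converged = !at_bound),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf(
    "exp_decay_fit: tau = %.3g ms (A = %.3g, c = %.3g, rss = %.3g)%s\n",
    x$tau_ms, x$amplitude, x$offset, x$rss,
    if (x$converged) "" else " [flagged]"))
  invisible(x)
}

#' One-call autocorrelation timescale estimate
#'
#' @param x numeric binned counts or single-row [spike_raster()].
#' @param bin_width_s bin width, seconds (from the raster if supplied).
#' @param max_lag_s maximum ACF lag, seconds.
#' @param ... passed to [fit_exp_decay()].
#' @return List: `tau_ms`, `fit` (the `exp_decay_fit`), `acf`.
#' @export
estimate_tau_acf <- function(x, bin_width_s = NULL, max_lag_s = 3.0, ...) {
  af <- compute_acf(x, bin_width_s, max_lag_s)
  fit <- fit_exp_decay(af, ...)
  list(tau_ms = fit$tau_ms, fit = fit, acf = af)
}
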