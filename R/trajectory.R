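#' Outlier-filter configuration for timescale estimates
#'
#' Defaults follow the published outlier ladders: extreme knee-frequency
#' bounds (greater than 100 Hz or less than 0.01 Hz removed), a
#' per-timepoint 4-SD cut in log10 space for MEA-style data, and a 100-ms
#' timescale cap for single-unit culture data.
#'
#' @param knee_hi,knee_lo knee-frequency bounds, Hz.
#' @param sd_limit per-timepoint SD limit applied to log10 timescales.
#' @param rat_tau_cap_ms timescale cap for the single-unit culture style,
#'   ms.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(knee_hi = 100, knee_lo = 0.01, sd_limit = 4,
                          rat_tau_cap_ms = 100) {
  if (knee_lo >= knee_hi) stop("'knee_lo' must be below 'knee_hi'")
  if (sd_limit <= 0) stop("'sd_limit' must be positive")
  structure(list(knee_hi = knee_hi, knee_lo = knee_lo, sd_limit = sd_limit,
                 rat_tau_cap_ms = rat_tau_cap_ms),
            class = "filter_config")
}

#' Remove outlier timescale estimates
#'
#' Two dataset styles are supported. `"organoid"` (MEA multiunit):
#' estimates whose knee frequency falls outside `[knee_lo, knee_hi]` (or
#' is not finite) are removed; the survivors are log10-transformed and,
#' per timepoint, values more than `sd_limit` standard deviations from
#' the timepoint mean are removed (the SD step is skipped, and logged,
#' at timepoints with fewer than 3 survivors). `"rat"` (single-unit
#' cultures): estimates with `tau_ms` above `rat_tau_cap_ms` are removed,
#' then estimates are averaged across units within each culture
#' (`source_id`) per timepoint.
#'
#' @param estimates data frame of timescale estimates with columns
#'   `tau_ms`, `timepoint_days`, and (for the organoid style)
#'   `knee_freq_hz`, (for the rat style) `source_id`.
#' @param cfg a [filter_config()].
#' @param dataset_style `"organoid"` or `"rat"`.
#' @return List: `kept` (filtered estimates; for `"rat"`, per-culture
#'   means), `removed` (removed rows with a `stage` column), `log`
#'   (data frame of per-stage in/out counts and notes). At every stage,
#'   input count = survivors + removals.
#' @export
filter_outliers <- function(estimates, cfg = filter_config(),
                            dataset_style = c("organoid", "rat")) {
  dataset_style <- match.arg(dataset_style)
  stopifnot(is.data.frame(estimates))
  log_rows <- list()
  removed <- estimates[0, , drop = FALSE]
  removed$stage <- character(0)
  if (nrow(estimates) == 0L)
    return(list(kept = estimates, removed = removed,
                log = data.frame(stage = character(), n_in = integer(),
                                 n_removed = integer(), note = character())))
  add_log <- function(stage, n_in, n_removed, note = "") {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_removed = n_removed, note = note)
  }
  if (dataset_style == "organoid") {
    stopifnot(all(c("tau_ms", "knee_freq_hz", "timepoint_days") %in%
                    names(estimates)))
    bad <- !is.finite(estimates$knee_freq_hz) |
      estimates$knee_freq_hz > cfg$knee_hi |
      estimates$knee_freq_hz < cfg$knee_lo
    if (any(bad)) {
      rm1 <- estimates[bad, , drop = FALSE]; rm1$stage <- "knee_bounds"
      removed <- rbind(removed, rm1)
    }
    add_log("knee_bounds", nrow(estimates), sum(bad))
    kept <- estimates[!bad, , drop = FALSE]
    # per-timepoint 4-SD cut in log10 space
    n_in <- nrow(kept)
    drop_idx <- logical(n_in)
    skipped <- character(0)
    for (tp in unique(kept$timepoint_days)) {
      idx <- which(kept$timepoint_days == tp)
      if (length(idx) < 3L) {
        skipped <- c(skipped, as.character(tp))
        next
      }
      lt <- log10(kept$tau_ms[idx])
      s <- sd(lt)
      if (s == 0) next
      z <- (lt - mean(lt)) / s
      drop_idx[idx[abs(z) > cfg$sd_limit]] <- TRUE
    }
    if (any(drop_idx)) {
      rm2 <- kept[drop_idx, , drop = FALSE]; rm2$stage <- "sd_limit"
      removed <- rbind(removed, rm2)
    }
    add_log("sd_limit", n_in, sum(drop_idx),
            if (length(skipped))
              paste0("skipped (<3 survivors) at timepoint(s): ",
                     paste(skipped, collapse = ", ")) else "")
    kept <- kept[!drop_idx, , drop = FALSE]
  } else {
    stopifnot(all(c("tau_ms", "source_id", "timepoint_days") %in%
                    names(estimates)))
    bad <- !is.finite(estimates$tau_ms) |
      estimates$tau_ms > cfg$rat_tau_cap_ms
    if (any(bad)) {
      rm1 <- estimates[bad, , drop = FALSE]; rm1$stage <- "tau_cap"
      removed <- rbind(removed, rm1)
    }
    add_log("tau_cap", nrow(estimates), sum(bad))
    kept <- estimates[!bad, , drop = FALSE]
    # average across units within a culture
    if (nrow(kept) > 0) {
      agg <- aggregate(tau_ms ~ timepoint_days + source_id, data = kept,
                       FUN = mean)
      add_log("culture_mean", nrow(kept), 0,
              sprintf("%d culture-timepoint mean(s)", nrow(agg)))
      kept <- agg
    }
  }
  rownames(kept) <- NULL
  list(kept = kept, removed = removed, log = do.call(rbind, log_rows))
}

#' Aggregate timescale estimates into a developmental trajectory
#'
#' Per-timepoint mean, SD and count of the timescale values, sorted by
#' timepoint. The trajectory models are fit to these means by default.
#'
#' @param estimates data frame with `timepoint_days` and `tau_ms` (e.g.
#'   `filter_outliers(...)$kept`).
#' @return Data frame: `timepoint_days`, `mean_tau_ms`, `sd_tau_ms`
#'   (0 when `n = 1`), `n`.
#' @export
aggregate_trajectory <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("timepoint_days", "tau_ms") %in% names(estimates)))
  if (nrow(estimates) == 0L)
    return(data.frame(timepoint_days = numeric(), mean_tau_ms = numeric(),
                      sd_tau_ms = numeric(), n = integer()))
  tps <- sort(unique(estimates$timepoint_days))
  out <- do.call(rbind, lapply(tps, function(tp) {
    v <- estimates$tau_ms[estimates$timepoint_days == tp]
    data.frame(timepoint_days = tp, mean_tau_ms = mean(v),
               sd_tau_ms = if (length(v) > 1) sd(v) else 0,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

traj_n_params <- c(constant = 1L, sigmoid = 4L, gaussian = 4L)

#' Fit a developmental-trajectory model
#'
#' Least-squares fit of one of three hypothesized trajectory shapes to
#' timescale data over time: constant (`c`; the fit is exactly the sample
#' mean), sigmoid (`a + b / (1 + exp(-(t - t0)/s))`: increase to a
#' plateau) or Gaussian (`a * exp(-(t - mu)^2/(2 sigma^2)) + c`: increase
#' then decrease). Initial guesses are data-driven (sigmoid: `t0` at the
#' midpoint of the time range, `a` the first value, `b` the value range;
#' Gaussian: `mu` at the argmax timepoint, `sigma` a quarter of the time
#' range, `c` the minimum), with jittered multi-starts on failure.
#'
#' @param data either an [aggregate_trajectory()] table (fits the
#'   per-timepoint means, the default target) or any data frame with
#'   `timepoint_days` and a value column (`mean_tau_ms` or `tau_ms`), e.g.
#'   the unaggregated estimates when fitting all points.
#' @param family `"constant"`, `"sigmoid"` or `"gaussian"`.
#' @return Object of class `trajectory_fit`: `family`, `params` (named),
#'   `rss`, `n_points`, `n_params`, `fitted` (function of time),
#'   `converged`.
#' @export
fit_trajectory <- function(data, family = c("constant", "sigmoid",
                                            "gaussian")) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data), "timepoint_days" %in% names(data))
  ycol <- intersect(c("mean_tau_ms", "tau_ms", "value"), names(data))[1]
  if (is.na(ycol)) stop("no value column (mean_tau_ms/tau_ms/value) found")
  t <- data$timepoint_days
  y <- data[[ycol]]
  n <- length(y)
  np <- traj_n_params[[family]]
  if (n <= np) stop("need more points than parameters")
  mk <- function(params, rss, converged) {
    structure(list(family = family, params = params, rss = rss,
                   n_points = n, n_params = np,
                   fitted = function(tt) tau_trajectory(family, params, tt),
                   data = data.frame(timepoint_days = t, value = y),
                   converged = converged),
              class = "trajectory_fit")
  }
  if (family == "constant") {
    cbar <- mean(y)
    return(mk(list(c = cbar), sum((y - cbar)^2), TRUE))
  }
  tr <- diff(range(t)); yr <- diff(range(y))
  # identifiability: a trajectory feature narrower than the sampling
  # interval is indistinguishable from single-timepoint noise, so the
  # Gaussian width is bounded below by the median timepoint spacing and
  # the sigmoid transition scale by a quarter of it
  spacing <- median(diff(sort(unique(t))))
  if (family == "sigmoid") {
    init <- c(a = y[which.min(t)], b = if (yr != 0) yr else 1,
              t0 = mean(range(t)), s = max(tr / 8, spacing / 4))
    lower <- c(-Inf, -Inf, min(t) - tr, spacing / 4)
    upper <- c(Inf, Inf, max(t) + tr, tr * 10)
    fn <- function(th) {
      pr <- th[1] + th[2] / (1 + exp(-(t - th[3]) / th[4]))
      sum((y - pr)^2)
    }
    nm <- c("a", "b", "t0", "s")
  } else {
    init <- c(a = if (yr != 0) yr else 1, mu = t[which.max(y)],
              sigma = max(tr / 4, spacing), c = min(y))
    lower <- c(-Inf, min(t) - tr, spacing, -Inf)
    upper <- c(Inf, max(t) + tr, tr * 10, Inf)
    fn <- function(th) {
      pr <- th[1] * exp(-(t - th[2])^2 / (2 * th[3]^2)) + th[4]
      sum((y - pr)^2)
    }
    nm <- c("a", "mu", "sigma", "c")
  }
  best <- NULL
  set <- list(init)
  for (j in 1:6)
    set[[j + 1L]] <- init * (1 + 0.3 * sin(j * seq_along(init) * 2.3)) +
      0.05 * j * abs(init)
  for (s0 in set) {
    r <- tryCatch(nlminb(s0, fn, lower = lower, upper = upper,
                         control = list(iter.max = 1000)),
                  error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$objective < best$objective))
      best <- r
  }
  if (is.null(best)) {
    warning("trajectory fit failed to converge; flagged")
    return(mk(setNames(as.list(rep(NaN, np)), nm), NaN, FALSE))
  }
  mk(setNames(as.list(best$par), nm), best$objective,
     best$convergence %in% c(0, 1))
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("trajectory_fit (%s): rss = %.4g on %d point(s); params: %s%s\n",
              x$family, x$rss, x$n_points,
              paste(names(x$params),
                    signif(unlist(x$params), 4), sep = "=", collapse = ", "),
              if (x$converged) "" else " [flagged]"))
  invisible(x)
}

#' Pairwise F test between trajectory fits
#'
#' For nested models (different parameter counts) computes the standard
#' extra-sum-of-squares F ratio
#' `F = ((rss_r - rss_f)/(df_r - df_f)) / (rss_f / df_f)` with
#' `df_i = n - n_params_i` and an upper-tail p value. For equal-complexity
#' models (sigmoid vs Gaussian, both 4 parameters) a nested test has zero
#' numerator degrees of freedom, so a two-sided variance-ratio F test
#' `F = (rss_a/df_a) / (rss_b/df_b)` is reported instead.
#'
#' @param fit_a,fit_b `trajectory_fit` objects on the same data; for the
#'   nested case, either order is accepted (the restricted model is the
#'   one with fewer parameters).
#' @return List of class `f_comparison`: `model_a`, `model_b`, `f_ratio`,
#'   `df_num`, `df_den`, `p_value`, `type` (`"nested"` or
#'   `"variance_ratio"`), `flagged` (TRUE when the full model has zero
#'   residual, giving an infinite F).
#' @export
f_test <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "trajectory_fit"),
            inherits(fit_b, "trajectory_fit"))
  if (fit_a$n_points != fit_b$n_points)
    stop("fits must be on identical data")
  n <- fit_a$n_points
  if (fit_a$n_params != fit_b$n_params) {
    r <- if (fit_a$n_params < fit_b$n_params) fit_a else fit_b
    f_ <- if (fit_a$n_params < fit_b$n_params) fit_b else fit_a
    df_r <- n - r$n_params; df_f <- n - f_$n_params
    if (f_$rss == 0) {
      fr <- if (r$rss == 0) 0 else Inf
      return(structure(list(model_a = r$family, model_b = f_$family,
                            f_ratio = fr, df_num = df_r - df_f,
                            df_den = df_f,
                            p_value = if (is.infinite(fr)) 0 else 1,
                            type = "nested", flagged = TRUE),
                       class = "f_comparison"))
    }
    fr <- ((r$rss - f_$rss) / (df_r - df_f)) / (f_$rss / df_f)
    fr <- max(0, fr)
    p <- pf(fr, df_r - df_f, df_f, lower.tail = FALSE)
    structure(list(model_a = r$family, model_b = f_$family, f_ratio = fr,
                   df_num = df_r - df_f, df_den = df_f, p_value = p,
                   type = "nested", flagged = FALSE),
              class = "f_comparison")
  } else {
    df_a <- n - fit_a$n_params; df_b <- n - fit_b$n_params
    if (fit_b$rss == 0)
      return(structure(list(model_a = fit_a$family, model_b = fit_b$family,
                            f_ratio = Inf, df_num = df_a, df_den = df_b,
                            p_value = 0, type = "variance_ratio",
                            flagged = TRUE),
                       class = "f_comparison"))
    fr <- (fit_a$rss / df_a) / (fit_b$rss / df_b)
    p <- 2 * min(pf(fr, df_a, df_b), pf(fr, df_a, df_b, lower.tail = FALSE))
    p <- min(1, p)
    structure(list(model_a = fit_a$family, model_b = fit_b$family,
                   f_ratio = fr, df_num = df_a, df_den = df_b, p_value = p,
                   type = "variance_ratio", flagged = FALSE),
              class = "f_comparison")
  }
}

#' @export
print.f_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: F(%g, %g) = %.4g, p = %.4g (%s)%s\n",
              x$model_b, x$model_a, x$df_num, x$df_den, x$f_ratio,
              x$p_value, x$type, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Postnatal-equivalence day for dissociated cultures
#'
#' Converts days in vitro to an estimated postnatal day:
#' `postnatal_day = divs - (gestation_days - extraction_day)`. With the
#' rat defaults (23-day gestation, embryonic-day-18 extraction) this is
#' `divs - 5`, mapping in vitro day 6 to postnatal day 1 and in vitro day
#' 35 to postnatal day 30.
#'
#' @param divs days in vitro (vectorized).
#' @param gestation_days species gestation period, days.
#' @param extraction_day embryonic day of tissue extraction.
#' @return Integer postnatal-equivalence day(s); negative results (a
#'   pre-birth equivalence) are an error.
#' @export
postnatal_day <- function(divs, gestation_days = 23, extraction_day = 18) {
  out <- divs - (gestation_days - extraction_day)
  if (any(out < 0))
    stop("postnatal equivalence undefined (negative) for divs < ",
         gestation_days - extraction_day)
  out
}

#' Compare timescale distributions at two timepoints
#'
#' Pooled-variance two-sample t test (two-sided), e.g. to contrast the
#' distributions at the peak and final timepoints of a trajectory.
#'
#' @param values_a,values_b numeric samples (each of length >= 2).
#' @return List: `t`, `df` (`n_a + n_b - 2`), `p_value`, group means.
#' @export
compare_endpoints <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("both samples must have at least 2 values")
  ht <- t.test(values_a, values_b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(values_a),
       mean_b = mean(values_b))
}
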