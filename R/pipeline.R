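#' Pipeline configuration
#'
#' Bundles the per-stage configurations for [run_pipeline()]. The input is
#' either a synthetic developmental study (a
#' [trajectory_study_config()]) or a table of spike-time files
#' (`spike_tables`: data frame with `path`, `timepoint_days`, optional
#' `source_id`), e.g. single-unit culture exports loaded through the
#' generic delimited-text reader.
#'
#' @param study a [trajectory_study_config()], or `NULL` when reading
#'   spike tables.
#' @param spike_tables data frame describing spike-time table files, or
#'   `NULL`.
#' @param dataset_style `"synthetic"`, `"organoid"` or `"rat"`; controls
#'   the outlier ladder. Synthetic studies use the organoid-style ladder.
#' @param methods timescale estimators to run (`"spectral"`, `"acf"`).
#' @param spectral spectral settings, a [spectral_config()].
#' @param filters outlier settings, a [filter_config()].
#' @param preprocess a [preprocess_config()] (bin width for the table
#'   path).
#' @param families trajectory families to fit and compare.
#' @param signal which simulated signal the estimators see:
#'   `"probability"` (the latent synaptic-activity trace; default) or
#'   `"spikes"` (the Bernoulli train). See the methods vignette for the
#'   point-process noise-floor tradeoff.
#' @param out_dir optional output directory for artifacts (TSV tables +
#'   JSON report/manifest).
#' @param seed global pipeline seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(study = NULL, spike_tables = NULL,
                            dataset_style = c("synthetic", "organoid", "rat"),
                            methods = c("spectral", "acf"),
                            spectral = spectral_config(),
                            filters = filter_config(),
                            preprocess = preprocess_config(),
                            families = c("constant", "sigmoid", "gaussian"),
                            signal = c("probability", "spikes"),
                            out_dir = NULL, seed = NULL) {
  dataset_style <- match.arg(dataset_style)
  signal <- match.arg(signal)
  methods <- match.arg(methods, several.ok = TRUE)
  families <- match.arg(families, c("constant", "sigmoid", "gaussian"),
                        several.ok = TRUE)
  if (is.null(study) == is.null(spike_tables))
    stop("supply exactly one of 'study' or 'spike_tables'")
  if (!is.null(study)) stopifnot(inherits(study, "trajectory_study_config"))
  if (!is.null(spike_tables)) {
    stopifnot(is.data.frame(spike_tables),
              all(c("path", "timepoint_days") %in% names(spike_tables)))
    missing <- !file.exists(spike_tables$path)
    if (any(missing))
      stop("missing input file(s): ",
           paste(spike_tables$path[missing], collapse = ", "))
  }
  structure(list(study = study, spike_tables = spike_tables,
                 dataset_style = dataset_style, methods = methods,
                 spectral = spectral, filters = filters,
                 preprocess = preprocess, families = families,
                 signal = signal, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full timescale-trajectory pipeline
#'
#' Executes simulate/load, timescale estimation (spectral and/or ACF
#' method), outlier filtering, trajectory aggregation, model fitting for
#' the requested families, and pairwise F comparisons, and assembles a
#' report with a provenance manifest (parameters, seed, per-stage counts).
#' Reruns with the same configuration reproduce identical outputs.
#'
#' The selected model is the constant unless a 4-parameter family beats it
#' (nested F test, p below 0.05); when both sigmoid and Gaussian beat it,
#' the one with the lower residual sum of squares is selected.
#'
#' @param cfg a [pipeline_config()].
#' @return List of class `pipeline_report`: `estimates`, `filtered`
#'   (kept/removed/log), `trajectory` (aggregate table), `fits`,
#'   `comparisons`, `selected_model`, `manifest`, and `truth` for
#'   synthetic studies.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  manifest <- list(package_version = as.character(utils::packageVersion("spiketau")),
                   seed = cfg$seed, dataset_style = cfg$dataset_style,
                   methods = cfg$methods, families = cfg$families,
                   signal = cfg$signal, stages = list())
  truth <- NULL
  if (!is.null(cfg$study)) {
    study_cfg <- cfg$study
    if (!is.null(cfg$seed)) study_cfg$seed <- cfg$seed
    study <- simulate_study(study_cfg, generate_spikes = TRUE)
    truth <- study$truth
    rows <- list()
    for (i in seq_along(study_cfg$timepoints)) {
      for (ch in seq_len(study_cfg$channels_per_timepoint)) {
        sim <- study$sims[[i]][[ch]]
        sig <- if (cfg$signal == "probability") sim$probability
          else as.numeric(sim$raster$counts[1L, ])
        fs <- sim$cfg$fs_hz
        if ("spectral" %in% cfg$methods) {
          est <- estimate_tau_spectral(sig, fs, cfg$spectral)
          rows[[length(rows) + 1L]] <- data.frame(
            timepoint_days = study_cfg$timepoints[i], source_id = "sim",
            channel = ch, method = "spectral", tau_ms = est$tau_ms,
            knee_freq_hz = est$knee_freq_hz)
        }
        if ("acf" %in% cfg$methods) {
          est <- estimate_tau_acf(sig, 1 / fs)
          rows[[length(rows) + 1L]] <- data.frame(
            timepoint_days = study_cfg$timepoints[i], source_id = "sim",
            channel = ch, method = "acf", tau_ms = est$tau_ms,
            knee_freq_hz = NA_real_)
        }
      }
    }
    estimates <- do.call(rbind, rows)
  } else {
    bw <- cfg$preprocess$bin_width_ms / 1000
    rows <- list()
    for (i in seq_len(nrow(cfg$spike_tables))) {
      tab <- read_spike_table(cfg$spike_tables$path[i])
      src <- if ("source_id" %in% names(cfg$spike_tables))
        cfg$spike_tables$source_id[i] else basename(cfg$spike_tables$path[i])
      raster <- bin_spikes(tab, bw)
      pop <- population_vector(raster)
      sig <- as.numeric(pop$counts[1L, ])
      fs <- 1 / bw
      if ("spectral" %in% cfg$methods) {
        est <- tryCatch(estimate_tau_spectral(sig, fs, cfg$spectral),
                        error = function(e) list(tau_ms = NaN,
                                                 knee_freq_hz = NaN))
        rows[[length(rows) + 1L]] <- data.frame(
          timepoint_days = cfg$spike_tables$timepoint_days[i],
          source_id = src, channel = NA, method = "spectral",
          tau_ms = est$tau_ms, knee_freq_hz = est$knee_freq_hz)
      }
      if ("acf" %in% cfg$methods) {
        est <- tryCatch(estimate_tau_acf(sig, bw),
                        error = function(e) list(tau_ms = NaN))
        rows[[length(rows) + 1L]] <- data.frame(
          timepoint_days = cfg$spike_tables$timepoint_days[i],
          source_id = src, channel = NA, method = "acf",
          tau_ms = est$tau_ms, knee_freq_hz = NA_real_)
      }
    }
    estimates <- do.call(rbind, rows)
  }
  manifest$stages$estimate <- list(n_estimates = nrow(estimates),
                                   n_failed = sum(!is.finite(estimates$tau_ms)))
  # trajectory statistics run on the spectral estimates when available
  primary <- if ("spectral" %in% cfg$methods) "spectral" else "acf"
  est_primary <- estimates[estimates$method == primary &
                             is.finite(estimates$tau_ms), , drop = FALSE]
  style <- if (cfg$dataset_style == "rat") "rat" else "organoid"
  filtered <- filter_outliers(est_primary, cfg$filters, style)
  manifest$stages$filter <- list(n_in = nrow(est_primary),
                                 n_kept = nrow(filtered$kept),
                                 n_removed = nrow(filtered$removed))
  trajectory <- aggregate_trajectory(filtered$kept)
  # families whose fits are not identifiable on this many timepoints are
  # skipped (with a warning) rather than aborting the whole report
  fits <- lapply(cfg$families, function(fam)
    tryCatch(fit_trajectory(trajectory, fam), error = function(e) {
      warning(sprintf("%s fit skipped: %s", fam, conditionMessage(e)))
      NULL
    }))
  names(fits) <- cfg$families
  fits <- Filter(Negate(is.null), fits)
  comparisons <- list()
  fams <- names(fits)
  if (length(fams) > 1) {
    for (i in seq_along(fams)) for (j in seq_along(fams)) {
      if (i >= j) next
      comparisons[[paste(fams[j], "vs", fams[i])]] <-
        f_test(fits[[fams[i]]], fits[[fams[j]]])
    }
  }
  selected <- if (length(fams) == 0) NA_character_ else "constant"
  if ("constant" %in% fams) {
    cands <- setdiff(fams, "constant")
    beat <- cands[vapply(cands, function(fm) {
      cmpx <- comparisons[[paste(fm, "vs", "constant")]]
      !is.null(cmpx) && is.finite(cmpx$p_value) && cmpx$p_value < 0.05
    }, logical(1))]
    if (length(beat) > 0) {
      rsss <- vapply(beat, function(fm) fits[[fm]]$rss, numeric(1))
      selected <- beat[which.min(rsss)]
    }
  } else if (length(fams) > 0) selected <- fams[1]
  manifest$stages$trajectory <- list(n_timepoints = nrow(trajectory),
                                     selected_model = selected)
  report <- structure(
    list(estimates = estimates, filtered = filtered, trajectory = trajectory,
         fits = fits, comparisons = comparisons, selected_model = selected,
         truth = truth, manifest = manifest),
    class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: %d estimate(s), %d timepoint(s); selected model: %s\n",
              nrow(x$estimates), nrow(x$trajectory), x$selected_model))
  for (cm in x$comparisons) print(cm)
  invisible(x)
}

# Artifact writer: delimited tables plus a JSON report/manifest.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$estimates, file.path(out_dir, "estimates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$trajectory, file.path(out_dir, "trajectory.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$truth))
    write.table(report$truth, file.path(out_dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  fits <- lapply(report$fits, function(fit)
    list(family = fit$family, params = fit$params, rss = fit$rss,
         n_points = fit$n_points, n_params = fit$n_params,
         converged = fit$converged))
  cmps <- lapply(report$comparisons, function(cm)
    list(model_a = cm$model_a, model_b = cm$model_b, f_ratio = cm$f_ratio,
         df_num = cm$df_num, df_den = cm$df_den, p_value = cm$p_value,
         type = cm$type))
  jsonlite::write_json(
    list(fits = fits, comparisons = cmps,
         selected_model = report$selected_model,
         filter_log = report$filtered$log, manifest = report$manifest),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, null = "null")
  invisible(out_dir)
}
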