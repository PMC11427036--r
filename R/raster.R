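#' Spike raster container
#'
#' A `spike_raster` holds binned spike counts for one or more units or
#' channels: an integer matrix `counts` (units x bins), the bin width in
#' seconds, the time origin, and unit/channel identifiers. It is the
#' universal internal representation that the binning, event-detection and
#' timescale-estimation stages operate on.
#'
#' @param counts numeric matrix (units x bins) of nonnegative counts; a
#'   vector is treated as a single-unit raster.
#' @param bin_width_s bin width in seconds (> 0).
#' @param t0_s time of the left edge of the first bin, seconds.
#' @param ids character or numeric unit/channel identifiers (one per row).
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(counts, bin_width_s, t0_s = 0, ids = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1L)
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop("'counts' must be a nonnegative numeric matrix")
  if (!is.numeric(bin_width_s) || length(bin_width_s) != 1L || bin_width_s <= 0)
    stop("'bin_width_s' must be a single positive number")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  if (length(ids) != nrow(counts))
    stop("'ids' must have one entry per raster row")
  structure(
    list(counts = counts, bin_width_s = bin_width_s, t0_s = t0_s,
         ids = as.character(ids)),
    class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "spike_raster: %d unit(s) x %d bins, bin width %g s, t0 = %g s, %d spikes\n",
    nrow(x$counts), ncol(x$counts), x$bin_width_s, x$t0_s, sum(x$counts)))
  invisible(x)
}

#' @export
dim.spike_raster <- function(x) dim(x$counts)

raster_duration_s <- function(raster) ncol(raster$counts) * raster$bin_width_s

raster_times <- function(raster) {
  raster$t0_s + (seq_len(ncol(raster$counts)) - 1L) * raster$bin_width_s
}

#' Bin a spike-time table into a raster
#'
#' Counts spikes per unit in half-open bins `[t0 + b*w, t0 + (b+1)*w)`.
#' Spikes outside `[t0, t0 + duration_s)` are dropped (with a warning), so
#' the total count of in-range spikes is conserved.
#'
#' @param spike_table data frame with columns `unit_id` and `time_s`.
#' @param bin_width_s bin width in seconds (> 0).
#' @param t0_s time origin (left edge of the first bin).
#' @param duration_s total binned duration in seconds; default spans the
#'   latest spike.
#' @param ids optional vector of unit ids fixing row order (and including
#'   silent units); default: sorted unique ids present in the table.
#' @return A [spike_raster()].
#' @export
bin_spikes <- function(spike_table, bin_width_s, t0_s = 0, duration_s = NULL,
                       ids = NULL) {
  stopifnot(is.data.frame(spike_table),
            all(c("unit_id", "time_s") %in% names(spike_table)))
  if (!is.numeric(bin_width_s) || length(bin_width_s) != 1L || bin_width_s <= 0)
    stop("'bin_width_s' must be positive")
  if (is.null(duration_s)) {
    duration_s <- if (nrow(spike_table) == 0L) bin_width_s
      else (max(spike_table$time_s) - t0_s) + bin_width_s / 2
  }
  n_bins <- max(1L, as.integer(ceiling(duration_s / bin_width_s - 1e-9)))
  if (is.null(ids)) {
    ids <- sort(unique(as.character(spike_table$unit_id)))
    if (length(ids) == 0L) ids <- "1"
  } else ids <- as.character(ids)
  counts <- matrix(0L, nrow = length(ids), ncol = n_bins)
  if (nrow(spike_table) > 0L) {
    b <- floor((spike_table$time_s - t0_s) / bin_width_s)
    keep <- b >= 0 & b < n_bins
    if (any(!keep))
      warning(sprintf("%d spike(s) outside [t0, t0 + duration) dropped",
                      sum(!keep)))
    row <- match(as.character(spike_table$unit_id), ids)
    keep <- keep & !is.na(row)
    if (any(keep)) {
      idx <- (b[keep]) * length(ids) + row[keep]   # column-major linear index
      tab <- tabulate(idx, nbins = length(ids) * n_bins)
      counts <- matrix(tab, nrow = length(ids), ncol = n_bins)
    }
  }
  spike_raster(counts, bin_width_s, t0_s, ids)
}

#' Rebin a raster into coarser bins
#'
#' Sums counts over consecutive groups of bins; the new bin width must be
#' an integer multiple of the old one. A trailing partial bin is dropped.
#'
#' @param raster a [spike_raster()].
#' @param bin_width_s new bin width, seconds.
#' @return A [spike_raster()] at the coarser binning.
#' @export
rebin_raster <- function(raster, bin_width_s) {
  stopifnot(inherits(raster, "spike_raster"))
  fac <- bin_width_s / raster$bin_width_s
  if (abs(fac - round(fac)) > 1e-6 || fac < 1)
    stop("new bin width must be an integer multiple of the old one")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(raster)
  n_new <- ncol(raster$counts) %/% fac
  idx <- rep(seq_len(n_new), each = fac)
  counts <- t(apply(raster$counts[, seq_len(n_new * fac), drop = FALSE], 1,
                    function(row) as.numeric(rowsum(row, idx))))
  spike_raster(counts, bin_width_s, raster$t0_s, raster$ids)
}

#' Population spiking vector
#'
#' Sums spike counts across all units/channels of a raster, preserving
#' binning. This is the population vector that network-event detection and
#' the population-level timescale estimates operate on.
#'
#' @param raster a [spike_raster()].
#' @return A single-row [spike_raster()] with id `"population"`.
#' @export
population_vector <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  spike_raster(matrix(colSums(raster$counts), nrow = 1L),
               raster$bin_width_s, raster$t0_s, ids = "population")
}

#' Read a delimited spike-time table
#'
#' Generic loader for two-column spike-time text files (`unit_id`,
#' `time_s` in seconds), the interchange format used for e.g. dissociated
#' -culture single-unit data sets. Lines starting with `#` are ignored; a
#' header row is auto-detected.
#'
#' @param path file path.
#' @param sep field separator (default: any whitespace).
#' @return data frame with columns `unit_id` (character), `time_s` (numeric).
#' @export
read_spike_table <- function(path, sep = "") {
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^\\s*#", first) & nzchar(trimws(first))]
  if (length(first) == 0L)
    return(data.frame(unit_id = character(), time_s = numeric()))
  toks <- strsplit(trimws(first[1]), if (sep == "") "\\s+" else sep)[[1]]
  header <- suppressWarnings(is.na(as.numeric(toks[length(toks)])))
  tab <- read.table(path, header = header, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("spike table must have >= 2 columns")
  out <- data.frame(unit_id = as.character(tab[[1]]),
                    time_s = as.numeric(tab[[2]]))
  if (any(!is.finite(out$time_s))) stop("non-numeric spike times in ", path)
  out
}

#' Write a spike-time table
#' @param spike_table data frame with `unit_id`, `time_s`.
#' @param path output file path.
#' @export
write_spike_table <- function(spike_table, path) {
  write.table(spike_table[, c("unit_id", "time_s")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a raster as plain text
#'
#' Serializes the counts matrix as TSV alongside a JSON sidecar
#' (`<path>.json`) carrying `bin_width_s`, `t0_s` and `channel_ids`.
#'
#' @param raster a [spike_raster()].
#' @param path counts TSV path; metadata goes to `paste0(path, ".json")`.
#' @return `write_raster`: the path, invisibly. `read_raster`: a
#'   [spike_raster()].
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  write.table(raster$counts, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- list(bin_width_s = raster$bin_width_s, t0_s = raster$t0_s,
               channel_ids = raster$ids)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  counts <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dimnames(counts) <- NULL
  spike_raster(counts, meta$bin_width_s, meta$t0_s, meta$channel_ids)
}
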