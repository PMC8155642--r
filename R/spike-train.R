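#' Spike train for one neuron ROI
#'
#' A spike train holds action-potential times for a single neuron, split by
#' recording epoch (one epoch = one contiguous movie acquisition; recordings
#' here are typically six 10 s movies at 500 Hz). Times are in milliseconds
#' relative to the start of their epoch. Optional per-spike signal-to-noise
#' ratios and peak dF/F amplitudes travel with the times.
#'
#' @param roi_id Character identifier of the neuron ROI.
#' @param times List with one sorted numeric vector of spike times (ms) per
#'   epoch. A plain numeric vector is treated as a single epoch.
#' @param epoch_durations_ms Numeric vector of epoch durations (ms), one per
#'   epoch.
#' @param snr Optional list matching `times` with per-spike SNR values.
#' @param amplitude Optional list matching `times` with per-spike peak dF/F.
#' @param cell_type One of `"inhibitory"`, `"DGC"`, `"CA1"`, `"CA3"`,
#'   `"unknown"`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(roi_id, times, epoch_durations_ms,
                        snr = NULL, amplitude = NULL,
                        cell_type = "unknown") {
  if (is.numeric(times)) times <- list(times)
  stopifnot(is.list(times), length(epoch_durations_ms) == length(times))
  if (any(epoch_durations_ms <= 0)) stop("epoch durations must be positive")
  cell_type <- match.arg(cell_type, cell_types())
  for (e in seq_along(times)) {
    t <- as.numeric(times[[e]])
    if (is.unsorted(t, strictly = TRUE)) {
      stop("spike times must be strictly increasing within epoch ", e)
    }
    if (length(t) && (t[1] < 0 || t[length(t)] >= epoch_durations_ms[e])) {
      stop("spike times must lie in [0, epoch duration) for epoch ", e)
    }
    times[[e]] <- t
  }
  if (!is.null(snr)) {
    if (is.numeric(snr)) snr <- list(snr)
    stopifnot(length(snr) == length(times))
  }
  if (!is.null(amplitude)) {
    if (is.numeric(amplitude)) amplitude <- list(amplitude)
    stopifnot(length(amplitude) == length(times))
  }
  structure(
    list(roi_id = as.character(roi_id), times = times,
         epoch_durations_ms = as.numeric(epoch_durations_ms),
         snr = snr, amplitude = amplitude, cell_type = cell_type),
    class = "spike_train")
}

#' Closed set of hippocampal cell-type labels
#' @return Character vector of admissible labels.
#' @export
cell_types <- function() c("inhibitory", "DGC", "CA1", "CA3", "unknown")

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s [%s]: %d spikes over %d epoch(s), %.1f s\n",
              x$roi_id, x$cell_type, n_spikes(x),
              length(x$times), total_duration_s(x)))
  invisible(x)
}

#' Total number of spikes across epochs
#' @param train A `spike_train`.
#' @return Integer count.
#' @export
n_spikes <- function(train) sum(lengths(train$times))

#' Total recorded duration in seconds
#'
#' Sum of epoch durations; gaps between sequentially recorded movies are
#' unknowable from the data and excluded by design.
#'
#' @param train A `spike_train`.
#' @return Seconds.
#' @export
total_duration_s <- function(train) sum(train$epoch_durations_ms) / 1000

#' Write spike trains to CSV
#'
#' Long format with one row per spike: `roi_id, epoch, time_ms, snr,
#' amplitude`. Quiescent ROIs contribute no rows but are listed in the
#' accompanying JSON bundle written next to the CSV (same path with
#' `.json` appended), which records epoch durations, cell types and the
#' MD5 checksum of the CSV for provenance.
#'
#' @param trains List of `spike_train` objects.
#' @param path Output CSV path.
#' @param config Optional list echoed into the JSON bundle.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(trains, path, config = NULL) {
  rows <- lapply(trains, function(tr) {
    do.call(rbind, lapply(seq_along(tr$times), function(e) {
      t <- tr$times[[e]]
      if (!length(t)) return(NULL)
      data.frame(roi_id = tr$roi_id, epoch = e, time_ms = t,
                 snr = if (is.null(tr$snr)) NA_real_ else tr$snr[[e]],
                 amplitude = if (is.null(tr$amplitude)) NA_real_
                             else tr$amplitude[[e]])
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(roi_id = character(), epoch = integer(),
                     time_ms = numeric(), snr = numeric(),
                     amplitude = numeric())
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    rois = lapply(trains, function(tr) {
      list(roi_id = tr$roi_id, cell_type = tr$cell_type,
           epoch_durations_ms = tr$epoch_durations_ms)
    }),
    config = config,
    csv_md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read spike trains written by [write_spike_csv()]
#' @param path CSV path (the `.json` bundle must sit alongside).
#' @return List of `spike_train` objects in the bundle's ROI order.
#' @export
read_spike_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rois <- meta$rois
  lapply(seq_len(nrow(rois)), function(i) {
    durs <- unlist(rois$epoch_durations_ms[i])
    id <- rois$roi_id[i]
    sub <- df[df$roi_id == id, , drop = FALSE]
    times <- lapply(seq_along(durs), function(e) sub$time_ms[sub$epoch == e])
    snr <- lapply(seq_along(durs), function(e) sub$snr[sub$epoch == e])
    amp <- lapply(seq_along(durs), function(e) sub$amplitude[sub$epoch == e])
    spike_train(id, times, durs, snr = snr, amplitude = amp,
                cell_type = rois$cell_type[i])
  })
}
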