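#' Average firing frequency of a spike train
#'
#' Total spike count across epochs divided by total recorded seconds (sum of
#' epoch durations; gaps between sequential movies are excluded).
#'
#' @param train A [spike_train()].
#' @return Frequency in Hz.
#' @export
average_frequency <- function(train) {
  dur <- total_duration_s(train)
  if (dur <= 0) stop("zero total duration")
  n_spikes(train) / dur
}

#' Inter-spike intervals and instantaneous frequencies
#'
#' ISIs are taken between consecutive spikes within the same epoch only;
#' intervals never bridge two movies. Instantaneous frequency is `1000 /
#' ISI_ms`, so a 20 ms interval reads as 50 Hz and a 330 ms interval as
#' about 3 Hz.
#'
#' @param train A [spike_train()].
#' @return A data frame with columns `epoch`, `isi_ms`, `inst_freq_hz`
#'   (zero rows when no epoch has two spikes).
#' @export
isi_and_instfreq <- function(train) {
  rows <- lapply(seq_along(train$times), function(e) {
    t <- train$times[[e]]
    if (length(t) < 2) return(NULL)
    isi <- diff(t)
    data.frame(epoch = e, isi_ms = isi, inst_freq_hz = 1000 / isi)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(epoch = integer(), isi_ms = numeric(),
                      inst_freq_hz = numeric())
  }
  out
}

#' Fraction of quiescent neurons
#'
#' A neuron is quiescent when it fires no spike across all epochs of the
#' session. Dentate granule cells are the usual suspects: roughly a quarter
#' of them stay silent in microisland recordings.
#'
#' @param trains List of [spike_train()] objects.
#' @param cell_type_filter Optional cell type; only trains with this label
#'   are considered.
#' @return Fraction in `[0, 1]`.
#' @export
quiescent_fraction <- function(trains, cell_type_filter = NULL) {
  if (!is.null(cell_type_filter)) {
    trains <- Filter(function(tr) tr$cell_type == cell_type_filter, trains)
  }
  if (!length(trains)) stop("no trains after filtering")
  mean(vapply(trains, n_spikes, 1L) == 0)
}

#' Normalize values to a reference condition within each replicate
#'
#' Each value is divided by the mean of the reference condition inside its
#' own biological replicate, the convention used to pool developmental
#' time-course data across replicates (the reference condition then has mean
#' 1 in every replicate).
#'
#' @param df Data frame with columns `value`, `condition`, `replicate`.
#' @param reference_condition The condition used as the denominator; every
#'   replicate must contain it with a nonzero mean.
#' @return `df` with an added `value_norm` column.
#' @export
normalize_by_reference <- function(df, reference_condition) {
  stopifnot(all(c("value", "condition", "replicate") %in% names(df)))
  out <- df
  out$value_norm <- NA_real_
  for (rep_id in unique(df$replicate)) {
    in_rep <- df$replicate == rep_id
    ref <- df$value[in_rep & df$condition == reference_condition]
    if (!length(ref)) {
      stop("replicate ", rep_id, " lacks reference condition ",
           reference_condition)
    }
    if (mean(ref) == 0) stop("zero reference mean in replicate ", rep_id)
    out$value_norm[in_rep] <- df$value[in_rep] / mean(ref)
  }
  out
}

#' Per-ROI firing metrics table
#'
#' @param trains List of [spike_train()] objects.
#' @return Data frame with one row per ROI: `roi_id`, `cell_type`,
#'   `n_spikes`, `duration_s`, `avg_freq_hz`, `quiescent`.
#' @export
metrics_table <- function(trains) {
  do.call(rbind, lapply(trains, function(tr) {
    data.frame(roi_id = tr$roi_id, cell_type = tr$cell_type,
               n_spikes = n_spikes(tr),
               duration_s = total_duration_s(tr),
               avg_freq_hz = average_frequency(tr),
               quiescent = n_spikes(tr) == 0)
  }))
}

#' Export firing metrics as CSV
#'
#' Writes `metrics.csv` (one row per ROI plus per-cell-type summary rows
#' with mean, SEM and n of the average frequency) and a long-format
#' companion `isi.csv` (`roi_id, epoch, isi_ms, inst_freq_hz`). CSV is used
#' rather than a spreadsheet format so exports diff and round-trip exactly.
#'
#' @param trains List of [spike_train()] objects.
#' @param out_path Path of the metrics CSV; the ISI companion is written
#'   next to it as `<stem>_isi.csv`.
#' @return Invisible list with both paths.
#' @export
export_metrics <- function(trains, out_path) {
  if (length(trains)) {
    tab <- metrics_table(trains)
    tab <- cbind(row_type = "roi", tab, sem_freq_hz = NA_real_,
                 n = NA_integer_)
    for (ct in intersect(cell_types(), unique(tab$cell_type))) {
      v <- tab$avg_freq_hz[tab$row_type == "roi" & tab$cell_type == ct]
      tab <- rbind(tab, data.frame(
        row_type = "summary", roi_id = NA, cell_type = ct,
        n_spikes = NA, duration_s = NA, avg_freq_hz = mean(v),
        quiescent = NA,
        sem_freq_hz = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                      else NA_real_,
        n = length(v)))
    }
  } else {
    tab <- data.frame(row_type = character(), roi_id = character(),
                      cell_type = character(), n_spikes = integer(),
                      duration_s = numeric(), avg_freq_hz = numeric(),
                      quiescent = logical(), sem_freq_hz = numeric(),
                      n = integer())
  }
  utils::write.csv(tab, out_path, row.names = FALSE)
  isi <- do.call(rbind, lapply(trains, function(tr) {
    d <- isi_and_instfreq(tr)
    if (!nrow(d)) return(NULL)
    cbind(roi_id = tr$roi_id, d)
  }))
  if (is.null(isi)) {
    isi <- data.frame(roi_id = character(), epoch = integer(),
                      isi_ms = numeric(), inst_freq_hz = numeric())
  }
  isi_path <- file.path(dirname(out_path),
                        paste0(tools::file_path_sans_ext(basename(out_path)),
                               "_isi.csv"))
  utils::write.csv(isi, isi_path, row.names = FALSE)
  invisible(list(metrics = out_path, isi = isi_path))
}
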