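#' Monosynaptic lag window
#'
#' Directed lag range (ms) within which a spike in the target neuron is
#' counted as a candidate monosynaptic response to a spike in the source
#' neuron. The default 8-14 ms window is the peak-to-peak transmission delay
#' band identified from pooled lag histograms of these cultures; bounds are
#' inclusive.
#'
#' @param low_ms,high_ms Window bounds in ms, `0 < low < high`.
#' @return A `lag_window` object.
#' @export
lag_window <- function(low_ms = 8, high_ms = 14) {
  if (!(0 < low_ms && low_ms < high_ms)) stop("need 0 < low < high")
  structure(list(low_ms = low_ms, high_ms = high_ms), class = "lag_window")
}

#' Cross-correlation index (XCI) of directed functional connectivity
#'
#' `XCI(A -> B)` is the fraction of A's spikes that are followed by at least
#' one spike of B at a lag inside the window (same epoch; each source spike
#' counts at most once however many target spikes fall in its window). With
#' the monosynaptic 8-14 ms window it estimates the probability that an
#' action potential in A triggers one in B: 1 means every A spike is
#' answered, 0 means none is. Lags are signed `t_B - t_A` and strictly
#' positive here, so XCI is directional and `XCI(A -> B)` carries no
#' information about `XCI(B -> A)`.
#'
#' @param a Source [spike_train()]; must be non-empty for a defined value.
#' @param b Target [spike_train()] with the same epoch structure.
#' @param window A [lag_window()].
#' @return Value in `[0, 1]`, or NA with attribute `reason` when `a` is
#'   empty.
#' @export
xci <- function(a, b, window = lag_window()) {
  if (length(a$epoch_durations_ms) != length(b$epoch_durations_ms) ||
      any(a$epoch_durations_ms != b$epoch_durations_ms)) {
    stop("trains have mismatched epoch structure")
  }
  na <- n_spikes(a)
  if (na == 0) {
    return(structure(NA_real_, reason = "empty source train"))
  }
  hits <- 0L
  for (e in seq_along(a$times)) {
    ta <- a$times[[e]]; tb <- b$times[[e]]
    if (!length(ta) || !length(tb)) next
    # target spikes in [t + low, t + high], bounds inclusive
    nmatch <- findInterval(ta + window$high_ms, tb) -
      findInterval(ta + window$low_ms, tb, left.open = TRUE)
    hits <- hits + sum(nmatch >= 1L)
  }
  hits / na
}

#' Directed XCI matrix over all neuron pairs
#'
#' Autapses (self-connections) are excluded by construction: the diagonal is
#' never computed. Entries with an empty source train are undefined (NA),
#' not zero.
#'
#' @param trains List of >= 2 [spike_train()] objects.
#' @param window A [lag_window()].
#' @param island_id Identifier copied into the long-format table.
#' @return List with `matrix` (N x N directed, source = row), `window`,
#'   `n_source_spikes` (per-row denominators), and `table`, a long data
#'   frame `source_roi, target_roi, island_id, xci, n_source_spikes,
#'   defined, source_type, target_type`.
#' @export
xci_matrix <- function(trains, window = lag_window(), island_id = "island") {
  n <- length(trains)
  if (n < 2) stop("need at least two trains")
  ids <- vapply(trains, `[[`, "", "roi_id")
  types <- vapply(trains, `[[`, "", "cell_type")
  counts <- vapply(trains, n_spikes, 1L)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  rows <- vector("list", n * (n - 1))
  k <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      v <- xci(trains[[i]], trains[[j]], window)
      m[i, j] <- as.numeric(v)
      k <- k + 1L
      rows[[k]] <- data.frame(
        source_roi = ids[i], target_roi = ids[j], island_id = island_id,
        xci = as.numeric(v), n_source_spikes = counts[i],
        defined = !is.na(v), source_type = types[i], target_type = types[j])
    }
  }
  list(matrix = m, window = window, n_source_spikes = counts,
       table = do.call(rbind, rows))
}

#' Cell-type-resolved XCI summary
#'
#' Pools defined XCI values by ordered (source type, target type) pair,
#' across however many islands are present in the table; the unit of
#' analysis is the neuron pair. The excitatory-only view restricts both ends
#' to DGC/CA3/CA1, the profile used to ask whether native hippocampal wiring
#' (DGC -> CA3 -> CA1) is re-established in culture. Type pairs without a
#' defined value are reported with `n_pairs = 0` and NA mean, never as zero.
#'
#' @param xci_table Long-format table from [xci_matrix()], possibly rbind-ed
#'   over islands.
#' @param excitatory_only If TRUE keep only DGC/CA3/CA1 on both ends.
#' @return Data frame `source_type, target_type, mean_xci, sem, n_pairs`.
#' @export
celltype_xci_summary <- function(xci_table, excitatory_only = TRUE) {
  types <- if (excitatory_only) c("DGC", "CA3", "CA1") else cell_types()
  tab <- xci_table[xci_table$source_type %in% types &
                   xci_table$target_type %in% types, , drop = FALSE]
  grid <- expand.grid(source_type = types, target_type = types,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    v <- tab$xci[tab$source_type == grid$source_type[i] &
                 tab$target_type == grid$target_type[i] & tab$defined]
    data.frame(source_type = grid$source_type[i],
               target_type = grid$target_type[i],
               mean_xci = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               n_pairs = length(v))
  })
  do.call(rbind, out)
}

#' Lag-time histogram between spike-train pairs
#'
#' For every ordered pair (A, B) and every spike of A, each signed lag
#' `t_B - t_A` with absolute value at most `max_lag_ms` and both spikes in
#' the same epoch contributes one count. Bins are right-open, default 2 ms
#' wide (the frame period, since optically detected spike times are
#' quantized at frame resolution), and the pooled histogram is the sum over
#' ordered pairs. Because every unordered pair enters the pool once per
#' direction, the pooled signed histogram is symmetric about 0 by
#' construction; the `folded` histogram over |lag| is therefore the object
#' whose peaks are interpretable: a coincidence peak near 0 reflects common
#' drive, and secondary peaks reflect mono- and disynaptic transmission.
#'
#' @param trains List of >= 2 [spike_train()] objects.
#' @param max_lag_ms Largest absolute lag retained (ms).
#' @param bin_width_ms Bin width (ms, > 0).
#' @return List with `breaks` (bin edges from -max_lag to +max_lag),
#'   `pooled` (signed counts), `folded` (list `breaks` from 0 to max_lag and
#'   `counts` over |lag|), and `pairs`, a data frame `source_roi,
#'   target_roi, bin_low_ms, bin_high_ms, count` for each ordered pair.
#' @export
lag_histogram <- function(trains, max_lag_ms = 50, bin_width_ms = 2) {
  if (length(trains) < 2) stop("need at least two trains")
  if (bin_width_ms <= 0) stop("bin width must be > 0")
  ids <- vapply(trains, `[[`, "", "roi_id")
  breaks <- seq(-max_lag_ms, max_lag_ms, by = bin_width_ms)
  if (breaks[length(breaks)] < max_lag_ms) {
    breaks <- c(breaks, breaks[length(breaks)] + bin_width_ms)
  }
  nb <- length(breaks) - 1
  fbreaks <- seq(0, max_lag_ms, by = bin_width_ms)
  if (fbreaks[length(fbreaks)] < max_lag_ms) {
    fbreaks <- c(fbreaks, fbreaks[length(fbreaks)] + bin_width_ms)
  }
  nfb <- length(fbreaks) - 1
  pooled <- integer(nb)
  folded <- integer(nfb)
  rows <- list()
  for (i in seq_along(trains)) {
    for (j in seq_along(trains)) {
      if (i == j) next
      counts <- integer(nb)
      for (e in seq_along(trains[[i]]$times)) {
        ta <- trains[[i]]$times[[e]]; tb <- trains[[j]]$times[[e]]
        if (!length(ta) || !length(tb)) next
        lags <- as.vector(outer(tb, ta, `-`))
        lags <- lags[abs(lags) <= max_lag_ms]
        if (!length(lags)) next
        idx <- findInterval(lags, breaks, rightmost.closed = TRUE)
        counts <- counts + tabulate(idx, nbins = nb)
        fidx <- findInterval(abs(lags), fbreaks, rightmost.closed = TRUE)
        folded <- folded + tabulate(fidx, nbins = nfb)
      }
      pooled <- pooled + counts
      rows[[length(rows) + 1]] <- data.frame(
        source_roi = ids[i], target_roi = ids[j],
        bin_low_ms = breaks[-length(breaks)], bin_high_ms = breaks[-1],
        count = counts)
    }
  }
  list(breaks = breaks, pooled = pooled,
       folded = list(breaks = fbreaks, counts = folded),
       pairs = do.call(rbind, rows))
}
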