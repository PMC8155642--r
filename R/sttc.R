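#' Spike-time tiling coefficient between two spike trains
#'
#' The STTC is a firing-rate-insensitive correlation between two spike
#' trains. With `T_X` the fraction of total recording time lying within
#' `+/- delta_t` of any spike of train X (interval union, clipped at epoch
#' boundaries and summed over epochs) and `P_X` the fraction of X's spikes
#' lying within `+/- delta_t` of any spike of the other train (same epoch
#' only):
#'
#'   `STTC = 1/2 * ( (P_A - T_B) / (1 - P_A * T_B)
#'                 + (P_B - T_A) / (1 - P_B * T_A) )`
#'
#' The value is undefined (NA, with a `reason` attribute) when either train
#' is empty or a denominator vanishes; undefined results are deliberately
#' never coerced to 0, since silent quiescent-neuron zeros would bias
#' population summaries.
#'
#' @param a,b [spike_train()] objects sharing epoch structure and durations.
#' @param delta_t_ms Coincidence half-window in ms (> 0); default 10 ms, on
#'   the order of the monosynaptic lags seen in these cultures.
#' @return An `sttc_result` list: `value`, `t_a`, `t_b`, `p_a`, `p_b`,
#'   `delta_t_ms`, `defined`, `reason`.
#' @export
compute_sttc <- function(a, b, delta_t_ms = 10) {
  if (delta_t_ms <= 0) stop("delta_t_ms must be > 0")
  if (length(a$epoch_durations_ms) != length(b$epoch_durations_ms) ||
      any(a$epoch_durations_ms != b$epoch_durations_ms)) {
    stop("trains have mismatched epoch structure")
  }
  res <- function(value, ta, tb, pa, pb, reason = NA_character_) {
    structure(list(pair = c(a$roi_id, b$roi_id), value = value,
                   t_a = ta, t_b = tb, p_a = pa, p_b = pb,
                   delta_t_ms = delta_t_ms,
                   defined = !is.na(value), reason = reason),
              class = "sttc_result")
  }
  if (n_spikes(a) == 0 || n_spikes(b) == 0) {
    return(res(NA_real_, NA, NA, NA, NA, "empty train"))
  }
  ta <- tiling_fraction(a, delta_t_ms)
  tb <- tiling_fraction(b, delta_t_ms)
  pa <- proximity_proportion(a, b, delta_t_ms)
  pb <- proximity_proportion(b, a, delta_t_ms)
  d1 <- 1 - pa * tb
  d2 <- 1 - pb * ta
  if (d1 == 0 || d2 == 0) {
    return(res(NA_real_, ta, tb, pa, pb, "vanishing denominator"))
  }
  res(0.5 * ((pa - tb) / d1 + (pb - ta) / d2), ta, tb, pa, pb)
}

# Fraction of total recorded time covered by the union of [t - dt, t + dt]
# windows, clipped to [0, epoch duration] per epoch.
tiling_fraction <- function(train, dt) {
  covered <- 0
  for (e in seq_along(train$times)) {
    t <- train$times[[e]]
    if (!length(t)) next
    dur <- train$epoch_durations_ms[e]
    lo <- pmax(t - dt, 0)
    hi <- pmin(t + dt, dur)
    # union of sorted, possibly overlapping intervals
    start <- lo[1]; end <- hi[1]
    for (i in seq_along(lo)[-1]) {
      if (lo[i] <= end) end <- max(end, hi[i]) else {
        covered <- covered + (end - start)
        start <- lo[i]; end <- hi[i]
      }
    }
    covered <- covered + (end - start)
  }
  covered / sum(train$epoch_durations_ms)
}

# Fraction of x's spikes having a spike of `other` within +/- dt, same epoch.
proximity_proportion <- function(x, other, dt) {
  near <- 0L
  for (e in seq_along(x$times)) {
    t <- x$times[[e]]; o <- other$times[[e]]
    if (!length(t) || !length(o)) next
    hits <- findInterval(t + dt, o) -
      findInterval(t - dt, o, left.open = TRUE)
    near <- near + sum(hits >= 1L)
  }
  near / n_spikes(x)
}

#' Pairwise STTC matrix
#'
#' @param trains List of >= 2 [spike_train()] objects with shared epoch
#'   structure.
#' @param delta_t_ms Coincidence half-window (ms).
#' @return List with `matrix` (symmetric; diagonal 1 for non-empty trains,
#'   NA otherwise) and `table`, a long-format data frame of the unordered
#'   pairs with columns `roi_a, roi_b, delta_t_ms, sttc, t_a, t_b, p_a, p_b,
#'   defined`.
#' @export
pairwise_sttc <- function(trains, delta_t_ms = 10) {
  n <- length(trains)
  if (n < 2) stop("need at least two trains")
  ids <- vapply(trains, `[[`, "", "roi_id")
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m) <- ifelse(vapply(trains, n_spikes, 1L) > 0, 1, NA_real_)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- compute_sttc(trains[[i]], trains[[j]], delta_t_ms)
      m[i, j] <- m[j, i] <- r$value
      rows[[length(rows) + 1]] <- data.frame(
        roi_a = ids[i], roi_b = ids[j], delta_t_ms = delta_t_ms,
        sttc = r$value, t_a = r$t_a, t_b = r$t_b, p_a = r$p_a, p_b = r$p_b,
        defined = r$defined)
    }
  }
  list(matrix = m, table = do.call(rbind, rows))
}
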