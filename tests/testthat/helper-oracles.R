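# Independent oracles and fixture builders shared across the suite.

# --- STTC by brute-force grid discretization ------------------------------
# Tiling fraction and proximity computed on a fine time grid (default
# 0.1 ms), entirely independent of the interval-union implementation.
sttc_grid_oracle <- function(a, b, delta_t_ms, grid_ms = 0.1) {
  tile_cover <- function(times, dur) {
    g <- seq(grid_ms / 2, dur - grid_ms / 2, by = grid_ms)
    cov <- rep(FALSE, length(g))
    for (t in times) cov <- cov | (abs(g - t) <= delta_t_ms)
    mean(cov)
  }
  prox <- function(x, o) {
    if (!length(x)) return(NA_real_)
    hits <- vapply(x, function(t) any(abs(o - t) <= delta_t_ms), TRUE)
    mean(hits)
  }
  ta <- tb <- 0; wt <- 0
  pa_hits <- pa_n <- pb_hits <- pb_n <- 0
  for (e in seq_along(a$times)) {
    dur <- a$epoch_durations_ms[e]
    ta <- ta + tile_cover(a$times[[e]], dur) * dur
    tb <- tb + tile_cover(b$times[[e]], dur) * dur
    wt <- wt + dur
    for (t in a$times[[e]]) {
      pa_n <- pa_n + 1
      if (any(abs(b$times[[e]] - t) <= delta_t_ms)) pa_hits <- pa_hits + 1
    }
    for (t in b$times[[e]]) {
      pb_n <- pb_n + 1
      if (any(abs(a$times[[e]] - t) <= delta_t_ms)) pb_hits <- pb_hits + 1
    }
  }
  ta <- ta / wt; tb <- tb / wt
  pa <- pa_hits / pa_n; pb <- pb_hits / pb_n
  0.5 * ((pa - tb) / (1 - pa * tb) + (pb - ta) / (1 - pb * ta))
}

# --- XCI by O(n*m) double loop --------------------------------------------
xci_loop_oracle <- function(a, b, low, high) {
  hits <- 0L; n <- 0L
  for (e in seq_along(a$times)) {
    for (t in a$times[[e]]) {
      n <- n + 1L
      found <- FALSE
      for (u in b$times[[e]]) {
        lag <- u - t
        if (lag >= low && lag <= high) { found <- TRUE; break }
      }
      if (found) hits <- hits + 1L
    }
  }
  if (n == 0) NA_real_ else hits / n
}

# --- optimal 1-D 3-means by exhaustive contiguous partition ---------------
# In one dimension the optimal k-means partition is contiguous in sorted
# order; enumerate all split pairs with prefix sums.
best_3partition <- function(x) {
  s <- sort(x)
  n <- length(s)
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  seg_ss <- function(i, j) { # within-SS of s[i..j]
    sm <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - sm^2 / (j - i + 1)
  }
  best <- Inf; best_split <- c(NA, NA)
  for (i in 1:(n - 2)) {
    left <- seg_ss(1, i)
    for (j in (i + 1):(n - 1)) {
      tot <- left + seg_ss(i + 1, j) + seg_ss(j + 1, n)
      if (tot < best) { best <- tot; best_split <- c(i, j) }
    }
  }
  i <- best_split[1]; j <- best_split[2]
  list(centers = c(mean(s[1:i]), mean(s[(i + 1):j]), mean(s[(j + 1):n])),
       tot_withinss = best)
}

# --- fixtures -------------------------------------------------------------
poisson_train <- function(rate_hz, n_epochs = 1, dur_ms = 10000,
                          roi_id = "p", cell_type = "unknown") {
  times <- lapply(seq_len(n_epochs), function(e) {
    k <- stats::rpois(1, rate_hz * dur_ms / 1000)
    sort(stats::runif(k, 0, dur_ms))
  })
  spike_train(roi_id, times, rep(dur_ms, n_epochs), cell_type = cell_type)
}

# snap continuous ground-truth times to the frame grid used by the renderer
snap_to_frames <- function(train, frame_period_ms = 2) {
  times <- lapply(seq_along(train$times), function(e) {
    t <- round(train$times[[e]] / frame_period_ms) * frame_period_ms
    unique(pmin(t, train$epoch_durations_ms[e] - frame_period_ms))
  })
  spike_train(train$roi_id, times, train$epoch_durations_ms,
              cell_type = train$cell_type)
}

# constant-intensity test movie with an ROI square and background square
constant_movie <- function(n_frames = 60, h = 20, w = 30,
                           roi_value = 100, bg_value = 30) {
  fr <- array(bg_value, dim = c(n_frames, h, w))
  fr[, 3:8, 3:8] <- roi_value
  movie_stack(fr)
}

square_roi_set <- function() {
  roi_set("test", list(
    roi("cell1", "neuron", polygon = rbind(c(2, 2), c(8, 2), c(8, 8), c(2, 8))),
    roi("bg", "background",
        polygon = rbind(c(12, 12), c(18, 12), c(18, 18), c(12, 18)))))
}
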