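#' Default cell-type composition of a microisland
#'
#' Proportions of identified cells in patterned microisland cultures:
#' 34% dentate granule cells, 20% CA1, 30% CA3, 16% inhibitory interneurons.
#'
#' @return Named numeric vector summing to 1.
#' @export
type_proportions_default <- function() {
  c(DGC = 0.34, CA1 = 0.20, CA3 = 0.30, inhibitory = 0.16)
}

#' Default per-type spontaneous firing rates (Hz)
#'
#' Mean rates observed in microislands containing at least one interneuron:
#' inhibitory 1.4 Hz, DGC 0.4 Hz, CA1 0.9 Hz, CA3 1.1 Hz.
#'
#' @return Named numeric vector (Hz).
#' @export
base_rates_default <- function() {
  c(inhibitory = 1.4, DGC = 0.4, CA1 = 0.9, CA3 = 1.1)
}

#' Hippocampal transmission-weight preset
#'
#' Ordered type-pair table of per-spike transmission probabilities. The
#' native hippocampal axis DGC -> CA3 -> CA1 and the recurrent CA1 -> CA1
#' wiring seen in culture get the elevated weight; every other ordered pair
#' gets the background weight, modeling the high general interconnectivity
#' of these cultures.
#'
#' @param elevated Weight for the preferential pairs (default 0.25).
#' @param background Weight for all other pairs (default 0.08).
#' @return Data frame `source_type, target_type, weight` covering all
#'   ordered type pairs.
#' @export
hippocampal_weight_rules <- function(elevated = 0.25, background = 0.08) {
  types <- cell_types()[cell_types() != "unknown"]
  grid <- expand.grid(source_type = types, target_type = types,
                      stringsAsFactors = FALSE)
  grid$weight <- background
  pref <- rbind(c("DGC", "CA3"), c("CA3", "CA1"), c("CA1", "CA1"))
  for (i in seq_len(nrow(pref))) {
    grid$weight[grid$source_type == pref[i, 1] &
                grid$target_type == pref[i, 2]] <- elevated
  }
  grid
}

#' Sample a ground-truth microisland network
#'
#' Cell types are drawn multinomially from `type_proportions`; directed
#' transmission weights come from `weight_rules`, either as constants
#' (column `weight`) or as Beta draws (columns `shape1`, `shape2`).
#' The diagonal is zeroed: autapses are excluded throughout.
#'
#' The spike cascade is only stable when the weight matrix is subcritical
#' (spectral radius below 1), and constant per-pair weights grow the radius
#' linearly with network size, so the drawn matrix is rescaled whenever its
#' spectral radius exceeds `max_spectral_radius` (default 0.6, a strongly
#' recurrent but safely subcritical branching ratio). Rescaling is uniform,
#' preserving the relative preferential structure of the preset.
#'
#' @param n_neurons Number of neurons (microislands hold 10-25).
#' @param type_proportions Named proportions over cell types, summing to 1.
#' @param weight_rules Ordered type-pair table; see
#'   [hippocampal_weight_rules()].
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @param max_spectral_radius Largest admissible spectral radius; matrices
#'   above it are scaled down to it. Set to `Inf` to disable.
#' @return A `network_spec`: `cell_type` (character vector), `w` (n x n
#'   weight matrix, source = row).
#' @export
sample_network <- function(n_neurons,
                           type_proportions = type_proportions_default(),
                           weight_rules = hippocampal_weight_rules(),
                           seed = 1L, max_spectral_radius = 0.6) {
  if (abs(sum(type_proportions) - 1) > 1e-9) {
    stop("type proportions must sum to 1")
  }
  if (any(type_proportions < 0)) stop("negative type proportion")
  set.seed(seed)
  types <- sample(names(type_proportions), n_neurons, replace = TRUE,
                  prob = type_proportions)
  w <- matrix(0, n_neurons, n_neurons)
  for (i in seq_len(n_neurons)) {
    for (j in seq_len(n_neurons)) {
      if (i == j) next
      row <- weight_rules[weight_rules$source_type == types[i] &
                          weight_rules$target_type == types[j], , drop = FALSE]
      if (!nrow(row)) stop("no weight rule for ", types[i], " -> ", types[j])
      w[i, j] <- if (!is.null(row$shape1) && !is.na(row$shape1[1])) {
        stats::rbeta(1, row$shape1[1], row$shape2[1])
      } else row$weight[1]
    }
  }
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  if (n_neurons > 1 && is.finite(max_spectral_radius)) {
    rho <- max(Mod(eigen(w, only.values = TRUE)$values))
    if (rho > max_spectral_radius) w <- w * (max_spectral_radius / rho)
  }
  structure(list(cell_type = types, w = w, n_neurons = n_neurons),
            class = "network_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the standard recording design: six 10 s epochs at 500 Hz,
#' per-type spontaneous rates from [base_rates_default()], monosynaptic
#' transmission lags uniform on 8-14 ms, a 6 ms refractory guard (the
#' shortest ISI observed), and a 2.5-fold disinhibition of excitatory rates
#' in islands containing no inhibitory neuron.
#'
#' @param n_epochs Number of epochs.
#' @param epoch_duration_ms Epoch length (ms).
#' @param frame_period_ms Frame period (ms) used downstream when rendering.
#' @param base_rates_hz Named per-type rates (Hz).
#' @param lag_low_ms,lag_high_ms Transmission-lag support (ms).
#' @param lag_dist `"uniform"` (default) or `"truncnorm"` (normal centered
#'   on the window midpoint, sd a quarter of the width, truncated to the
#'   support) for robustness checks.
#' @param refractory_ms Minimum interval between retained spikes of one
#'   neuron; 0 disables.
#' @param disinhibition_factor Multiplier applied to excitatory base rates
#'   when the island has no inhibitory neuron.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_epochs = 6, epoch_duration_ms = 10000,
                       frame_period_ms = 2,
                       base_rates_hz = base_rates_default(),
                       lag_low_ms = 8, lag_high_ms = 14,
                       lag_dist = c("uniform", "truncnorm"),
                       refractory_ms = 6, disinhibition_factor = 2.5) {
  if (any(base_rates_hz < 0)) stop("rates must be >= 0")
  if (!(0 < lag_low_ms && lag_low_ms < lag_high_ms &&
        lag_high_ms < epoch_duration_ms)) {
    stop("lag support must lie within (0, epoch length)")
  }
  structure(list(n_epochs = n_epochs, epoch_duration_ms = epoch_duration_ms,
                 frame_period_ms = frame_period_ms,
                 base_rates_hz = base_rates_hz,
                 lag_low_ms = lag_low_ms, lag_high_ms = lag_high_ms,
                 lag_dist = match.arg(lag_dist),
                 refractory_ms = refractory_ms,
                 disinhibition_factor = disinhibition_factor),
            class = "sim_config")
}

draw_lag <- function(n, cfg) {
  if (cfg$lag_dist == "uniform") {
    stats::runif(n, cfg$lag_low_ms, cfg$lag_high_ms)
  } else {
    mid <- (cfg$lag_low_ms + cfg$lag_high_ms) / 2
    sd <- (cfg$lag_high_ms - cfg$lag_low_ms) / 4
    x <- stats::rnorm(n, mid, sd)
    while (any(bad <- x < cfg$lag_low_ms | x > cfg$lag_high_ms)) {
      x[bad] <- stats::rnorm(sum(bad), mid, sd)
    }
    x
  }
}

#' Simulate ground-truth spike trains from a microisland network
#'
#' Branching construction: each neuron fires background spikes as a
#' homogeneous Poisson process at its type's rate (times the disinhibition
#' factor for excitatory neurons when the island has no interneuron); every
#' spike of neuron i independently triggers a spike in each neuron j with
#' probability `w[i, j]`, at a lag drawn from the configured distribution,
#' and triggered spikes can themselves trigger further spikes (disynaptic
#' and longer chains). After the cascade, any spike falling within the
#' refractory period of its neuron's previous retained spike is discarded.
#' The weight matrix must be subcritical (spectral radius < 1), otherwise
#' the cascade is a runaway and the call errors.
#'
#' @param network A [sample_network()] result (or a list with `cell_type`
#'   and `w`).
#' @param config A [sim_config()].
#' @param seed RNG seed; output is deterministic given seed and config.
#' @return List with `trains` (list of [spike_train()]) and `ground_truth`,
#'   a data frame of retained spikes: `neuron, epoch, time_ms,
#'   parent_neuron, parent_time_ms, lag_ms` (`parent_neuron` NA for
#'   background spikes).
#' @export
simulate_spike_trains <- function(network, config = sim_config(), seed = 1L) {
  w <- network$w
  n <- nrow(w)
  if (max(Mod(eigen(w, only.values = TRUE)$values)) >= 1) {
    stop("unstable weight matrix: spectral radius must be < 1")
  }
  types <- network$cell_type
  rates <- config$base_rates_hz[types]
  rates[is.na(rates)] <- 0  # unknown types are silent background-wise
  if (!any(types == "inhibitory")) {
    exc <- types != "inhibitory"
    rates[exc] <- rates[exc] * config$disinhibition_factor
  }
  set.seed(seed)
  T_ms <- config$epoch_duration_ms
  gt <- list()
  for (ep in seq_len(config$n_epochs)) {
    # background generation, then breadth-wise cascade
    ev <- list()
    for (i in seq_len(n)) {
      k <- stats::rpois(1, rates[i] * T_ms / 1000)
      if (k) {
        ev[[length(ev) + 1]] <- data.frame(
          neuron = i, time_ms = sort(stats::runif(k, 0, T_ms)),
          parent_neuron = NA_integer_, parent_time_ms = NA_real_,
          lag_ms = NA_real_)
      }
    }
    frontier <- if (length(ev)) do.call(rbind, ev) else NULL
    all_ev <- frontier
    while (!is.null(frontier) && nrow(frontier)) {
      children <- list()
      for (r in seq_len(nrow(frontier))) {
        i <- frontier$neuron[r]
        hit <- which(stats::runif(n) < w[i, ])
        if (length(hit)) {
          lags <- draw_lag(length(hit), config)
          tt <- frontier$time_ms[r] + lags
          ok <- tt < T_ms
          if (any(ok)) {
            children[[length(children) + 1]] <- data.frame(
              neuron = hit[ok], time_ms = tt[ok],
              parent_neuron = i, parent_time_ms = frontier$time_ms[r],
              lag_ms = lags[ok])
          }
        }
      }
      frontier <- if (length(children)) do.call(rbind, children) else NULL
      if (!is.null(frontier)) all_ev <- rbind(all_ev, frontier)
    }
    if (is.null(all_ev)) next
    all_ev <- all_ev[order(all_ev$neuron, all_ev$time_ms), , drop = FALSE]
    if (config$refractory_ms > 0) {
      keep <- logical(nrow(all_ev))
      last <- rep(-Inf, n)
      for (r in seq_len(nrow(all_ev))) {
        i <- all_ev$neuron[r]
        if (all_ev$time_ms[r] - last[i] >= config$refractory_ms) {
          keep[r] <- TRUE
          last[i] <- all_ev$time_ms[r]
        }
      }
      all_ev <- all_ev[keep, , drop = FALSE]
    }
    all_ev$epoch <- ep
    gt[[length(gt) + 1]] <- all_ev
  }
  gt <- if (length(gt)) do.call(rbind, gt) else
    data.frame(neuron = integer(), time_ms = numeric(),
               parent_neuron = integer(), parent_time_ms = numeric(),
               lag_ms = numeric(), epoch = integer())
  trains <- lapply(seq_len(n), function(i) {
    times <- lapply(seq_len(config$n_epochs), function(ep) {
      sort(gt$time_ms[gt$neuron == i & gt$epoch == ep])
    })
    spike_train(paste0("n", i), times,
                rep(T_ms, config$n_epochs), cell_type = types[i])
  })
  list(trains = trains, ground_truth = gt, network = network,
       config = config, seed = seed)
}

#' Render dF/F traces from spike trains
#'
#' Inverse of the detection model: each spike paints an instantaneous rise
#' to amplitude `a` at its frame (spike times are snapped to the nearest
#' frame) followed by exponential decay with time constant `tau_ms`, on top
#' of additive white Gaussian noise. The defaults (a = 0.10 dF/F, tau = 4
#' ms, sigma = 0.01) give the amplitude-to-noise ratio of 10 typical of
#' good voltage-dye recordings, with transients confined to the 0-11% dF/F
#' display range.
#'
#' @param trains List of [spike_train()] objects (or a
#'   [simulate_spike_trains()] result).
#' @param amplitude Peak dF/F per spike (> 0).
#' @param tau_ms Decay time constant (ms).
#' @param sigma Noise standard deviation (dF/F, >= 0).
#' @param frame_period_ms Frame period (ms).
#' @param seed RNG seed for the noise.
#' @return List (one per neuron) of per-epoch dF/F vectors.
#' @export
render_traces <- function(trains, amplitude = 0.10, tau_ms = 4,
                          sigma = 0.01, frame_period_ms = 2, seed = 1L) {
  if (!is.null(trains$trains)) trains <- trains$trains
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  set.seed(seed)
  lapply(trains, function(tr) {
    lapply(seq_along(tr$times), function(e) {
      nfr <- round(tr$epoch_durations_ms[e] / frame_period_ms)
      y <- if (sigma > 0) stats::rnorm(nfr, 0, sigma) else numeric(nfr)
      for (t in tr$times[[e]]) {
        k <- min(max(round(t / frame_period_ms), 0), nfr - 1)  # 0-based frame
        idx <- (k + 1):nfr
        y[idx] <- y[idx] + amplitude *
          exp(-((idx - (k + 1)) * frame_period_ms) / tau_ms)
      }
      y
    })
  })
}

#' Render a synthetic voltage-imaging movie
#'
#' Paints disk somata at random non-overlapping positions in a wide-format
#' frame (default proportioned like the 2048 x 400 px acquisition) whose
#' pixel values follow `offset + f0 * (1 + dF/F)` inside somata and
#' `offset` elsewhere, so that [extract_traces()] with the true ROI masks
#' followed by [compute_dff()] recovers the rendered traces.
#'
#' @param dff_traces Output of [render_traces()].
#' @param dim_hw Frame size `c(rows, cols)`.
#' @param soma_radius_px Soma disk radius (px).
#' @param f0 Resting fluorescence of a soma (arbitrary units).
#' @param offset Background level added everywhere.
#' @param frame_period_ms,pixel_size_um Movie metadata.
#' @param epoch Which epoch of the traces to render.
#' @param seed RNG seed for soma placement.
#' @return List with `movie` (a [movie_stack()]) and `rois` (an
#'   [roi_set()] of the true soma masks plus a background ROI).
#' @export
render_movie <- function(dff_traces, dim_hw = c(80, 410),
                         soma_radius_px = 8, f0 = 100, offset = 30,
                         frame_period_ms = 2, pixel_size_um = 0.325,
                         epoch = 1, seed = 1L) {
  n <- length(dff_traces)
  h <- dim_hw[1]; w <- dim_hw[2]
  set.seed(seed)
  centers <- matrix(NA_real_, n, 2)
  r <- soma_radius_px
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in 1:100) {
      c_row <- stats::runif(1, r + 1, h - r)
      c_col <- stats::runif(1, r + 1, w * 0.8 - r)  # right fifth kept dark
      if (i == 1 ||
          all(sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                            matrix(c(c_row, c_col), i - 1, 2,
                                   byrow = TRUE))^2)) > 2 * r + 2)) {
        centers[i, ] <- c(c_row, c_col)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n, " non-overlapping somata; use fewer ",
           "neurons or a larger frame")
    }
  }
  rows <- matrix(rep(seq_len(h), w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  masks <- lapply(seq_len(n), function(i) {
    (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <= r^2
  })
  bg_mask <- matrix(FALSE, h, w)
  bg_mask[, floor(w * 0.9):w] <- TRUE
  nfr <- length(dff_traces[[1]][[epoch]])
  frames <- array(offset, dim = c(nfr, h, w))
  for (i in seq_len(n)) {
    vals <- offset + f0 * (1 + dff_traces[[i]][[epoch]])
    idx <- which(masks[[i]])
    for (p in idx) {
      pr <- (p - 1) %% h + 1
      pc <- (p - 1) %/% h + 1
      frames[, pr, pc] <- vals
    }
  }
  rois <- c(lapply(seq_len(n), function(i) {
    roi(paste0("n", i), "neuron", mask = masks[[i]])
  }), list(roi("bg", "background", mask = bg_mask)))
  list(movie = movie_stack(frames, frame_period_ms, pixel_size_um, epoch),
       rois = roi_set("synthetic", rois))
}

#' Write simulation ground truth to JSON
#' @param sim A [simulate_spike_trains()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  jsonlite::write_json(list(
    cell_type = sim$network$cell_type,
    w = sim$network$w,
    config = unclass(sim$config),
    seed = sim$seed,
    spikes = sim$ground_truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
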