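#' Extract background-corrected fluorescence traces from one movie
#'
#' For each neuron ROI and frame t the trace value is
#' `mean(ROI pixels at t) - mean(background ROI pixels at t)`. Frame-wise
#' subtraction (rather than a scalar offset) tracks illumination drift over
#' the acquisition. The uncorrected background trace is returned as an
#' attribute for quality control.
#'
#' @param movie A [movie_stack()].
#' @param rs An [roi_set()]; all ROIs must lie within the movie frame.
#' @return Numeric matrix, frames x neuron ROIs, with column names the ROI
#'   ids, attribute `background` the background-ROI mean trace, and attribute
#'   `frame_period_ms`.
#' @export
extract_traces <- function(movie, rs) {
  stopifnot(inherits(movie, "movie_stack"), inherits(rs, "roi_set"))
  d <- dim(movie$frames)
  hw <- d[2:3]
  flat <- matrix(movie$frames, nrow = d[1])  # frames x (h*w), column-major
  mean_in <- function(r) {
    m <- roi_mask(r, hw)
    check_roi_bounds(r, hw)
    rowMeans(flat[, as.vector(m), drop = FALSE])
  }
  bg <- mean_in(rs$background)
  out <- vapply(rs$neurons, function(r) mean_in(r) - bg, numeric(d[1]))
  out <- matrix(out, nrow = d[1],
                dimnames = list(NULL, vapply(rs$neurons, `[[`, "", "roi_id")))
  attr(out, "background") <- bg
  attr(out, "frame_period_ms") <- movie$frame_period_ms
  out
}

check_roi_bounds <- function(r, hw) {
  if (!is.null(r$polygon)) {
    x <- r$polygon[, 1]; y <- r$polygon[, 2]
    if (any(x < 0 | x > hw[2] | y < 0 | y > hw[1])) {
      stop("ROI ", r$roi_id, " lies (partly) outside the image")
    }
  }
  invisible(TRUE)
}

#' Convert raw traces to dF/F
#'
#' `dF/F(t) = (F(t) - F0) / F0` with the baseline F0 computed per epoch,
#' never across epochs (movies are separate acquisitions). Two baseline
#' modes are provided: the mean of the leading `n` frames (default n = 25,
#' mirroring the average-projection recipe used for display movies), or a
#' lower percentile of the whole epoch (robust when early frames contain
#' spikes).
#'
#' @param raw Numeric vector (one epoch) or list of per-epoch vectors of
#'   background-corrected fluorescence for a single ROI.
#' @param baseline_mode `"leading_frames"` or `"percentile"`.
#' @param n Number of leading frames for `"leading_frames"`.
#' @param p Percentile (0-100) for `"percentile"`.
#' @return Same shape as `raw`, dF/F values, with attribute `F0` holding the
#'   per-epoch baselines.
#' @export
compute_dff <- function(raw, baseline_mode = c("leading_frames", "percentile"),
                        n = 25, p = 20) {
  baseline_mode <- match.arg(baseline_mode)
  single <- is.numeric(raw)
  epochs <- if (single) list(raw) else raw
  f0 <- numeric(length(epochs))
  out <- vector("list", length(epochs))
  for (e in seq_along(epochs)) {
    f <- epochs[[e]]
    if (anyNA(f) || any(!is.finite(f))) stop("non-finite fluorescence in epoch ", e)
    f0[e] <- switch(baseline_mode,
      leading_frames = {
        if (length(f) < n) {
          stop("epoch ", e, " has ", length(f),
               " frames; need >= ", n, " for the leading-frames baseline")
        }
        mean(f[seq_len(n)])
      },
      percentile = stats::quantile(f, p / 100, names = FALSE))
    if (f0[e] <= 0) {
      stop("non-positive baseline F0 in epoch ", e,
           " (background over-subtraction?)")
    }
    out[[e]] <- (f - f0[e]) / f0[e]
  }
  res <- if (single) out[[1]] else out
  attr(res, "F0") <- f0
  res
}

#' Render an 8-bit dF/F display movie
#'
#' Reproduces the standard visualization recipe: F0 is the per-pixel mean of
#' the baseline frames, dF/F is clipped to `display_range` (default 0-11%)
#' and mapped linearly to 0-255, and each 8-bit frame is smoothed with a
#' Gaussian blur (default sigma 2 px) to aid visibility.
#'
#' @param movie A [movie_stack()] with more than `max(baseline_frames)` frames.
#' @param baseline_frames Indices (1-based) of the frames averaged into F0.
#' @param display_range dF/F values mapped to 0 and 255.
#' @param blur_sigma_px Gaussian blur sigma in pixels; 0 disables.
#' @return An 8-bit `movie_stack` of the same geometry.
#' @export
render_dff_movie <- function(movie, baseline_frames = 1:25,
                             display_range = c(0, 0.11), blur_sigma_px = 2) {
  d <- dim(movie$frames)
  if (any(baseline_frames < 1 | baseline_frames > d[1])) {
    stop("baseline frames out of range")
  }
  if (d[1] <= max(baseline_frames)) {
    stop("movie must extend beyond the baseline frames")
  }
  f0 <- apply(movie$frames[baseline_frames, , , drop = FALSE], c(2, 3), mean)
  if (any(f0 <= 0)) stop("non-positive per-pixel baseline")
  lo <- display_range[1]; hi <- display_range[2]
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) {
    dff <- (movie$frames[i, , ] - f0) / f0
    dff <- pmin(pmax(dff, lo), hi)
    fr <- (dff - lo) / (hi - lo) * 255
    if (blur_sigma_px > 0) fr <- gaussian_blur(fr, blur_sigma_px)
    out[i, , ] <- round(fr)
  }
  movie_stack(out, movie$frame_period_ms, movie$pixel_size_um, movie$epoch_id)
}

# Separable Gaussian blur with edge renormalization (kernel truncated at 3
# sigma and reweighted so flat regions stay flat at the borders).
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  blur1 <- function(m) {
    n <- nrow(m)
    acc <- matrix(0, n, ncol(m)); wt <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      src <- (1:n) + o
      ok <- src >= 1 & src <= n
      acc[ok, ] <- acc[ok, ] + k[o + r + 1] * m[src[ok], ]
      wt[ok, ] <- wt[ok, ] + k[o + r + 1]
    }
    acc / wt
  }
  t(blur1(t(blur1(img))))
}

#' Write per-ROI traces to CSV
#'
#' Columns `time_ms`, `epoch`, then one column per ROI id. Time is relative
#' to epoch start and quantized at the frame period.
#'
#' @param traces List (per epoch) of frames x ROI matrices, as produced by
#'   [extract_traces()] over an area's movies, or a single such matrix.
#' @param path Output CSV path.
#' @param frame_period_ms Frame period used for the time column.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path, frame_period_ms = 2) {
  if (!is.list(traces)) traces <- list(traces)
  rows <- lapply(seq_along(traces), function(e) {
    m <- traces[[e]]
    data.frame(time_ms = (seq_len(nrow(m)) - 1) * frame_period_ms,
               epoch = e, m, check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
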