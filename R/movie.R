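#' In-memory movie stack
#'
#' One recording epoch: a T x H x W array of pixel intensities with the frame
#' period and pixel size attached. Timing metadata always comes from the
#' caller (acquisition-software TIFF tags are not trusted); the conventional
#' acquisition here is 500 Hz (2 ms frames) with 0.325 um pixels.
#'
#' @param frames Numeric or integer array with dim (time, row, col).
#' @param frame_period_ms Frame period in milliseconds (> 0).
#' @param pixel_size_um Pixel edge length in micrometers (> 0).
#' @param epoch_id Small integer identifying the epoch within its area.
#' @return A `movie_stack` object.
#' @export
movie_stack <- function(frames, frame_period_ms = 2, pixel_size_um = 0.325,
                        epoch_id = 1L) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[1] < 1) stop("movie must contain at least one frame")
  if (frame_period_ms <= 0) stop("frame_period_ms must be > 0")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  structure(list(frames = frames,
                 frame_period_ms = as.numeric(frame_period_ms),
                 pixel_size_um = as.numeric(pixel_size_um),
                 epoch_id = as.integer(epoch_id)),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<movie_stack> %d frames of %d x %d px, %.3g ms/frame (%.3g s total)\n",
    d[1], d[2], d[3], x$frame_period_ms, d[1] * x$frame_period_ms / 1000))
  invisible(x)
}

#' Duration of a movie in milliseconds
#' @param movie A `movie_stack`.
#' @return Milliseconds covered by the stack.
#' @export
movie_duration_ms <- function(movie) dim(movie$frames)[1] * movie$frame_period_ms

#' Load a multi-frame grayscale TIFF movie
#'
#' Frames are returned in file order, which is taken to be acquisition order.
#' Integer TIFFs are read bit-exactly (no 0-1 rescaling). RGB or multi-channel
#' TIFFs are rejected: voltage-imaging movies are single-channel.
#'
#' @param path Path to a multi-frame grayscale TIFF.
#' @inheritParams movie_stack
#' @return A `movie_stack`.
#' @export
load_movie <- function(path, frame_period_ms = 2, pixel_size_um = 0.325,
                       epoch_id = 1L) {
  if (!file.exists(path)) stop("cannot read movie: ", path)
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  dims <- lapply(imgs, dim)
  if (any(vapply(dims, length, 1L) != 2)) {
    stop("not single-channel: ", path)
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    stop("frames of inconsistent shape in ", path)
  }
  h <- dims[[1]][1]; w <- dims[[1]][2]
  frames <- array(0, dim = c(length(imgs), h, w))
  for (i in seq_along(imgs)) frames[i, , ] <- imgs[[i]]
  movie_stack(frames, frame_period_ms, pixel_size_um, epoch_id)
}

#' Write a movie stack to a multi-frame TIFF
#'
#' Integer-valued stacks round-trip bit-exactly through 8- or 16-bit TIFF
#' (the native format of camera acquisitions); real-valued stacks already
#' normalized to `[0, 1]` can be written as 32-bit float, the only float
#' range the TIFF backend stores portably.
#'
#' @param movie A `movie_stack`.
#' @param path Output path.
#' @param bits One of 8, 16 (integer data in range) or 32 (float in
#'   `[0, 1]`).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, bits = 16) {
  fr <- movie$frames
  n <- dim(fr)[1]
  if (bits %in% c(8, 16)) {
    maxv <- 2^bits - 1
    if (any(fr < 0 | fr > maxv) || any(fr != round(fr))) {
      stop("integer TIFF requires integer samples in [0, ", maxv, "]")
    }
    imgs <- lapply(seq_len(n), function(i) fr[i, , ] / maxv)
    tiff::writeTIFF(imgs, path, bits.per.sample = bits)
  } else if (bits == 32) {
    if (any(fr < 0 | fr > 1)) {
      stop("float TIFF requires samples in [0, 1]")
    }
    imgs <- lapply(seq_len(n), function(i) fr[i, , ])
    tiff::writeTIFF(imgs, path, bits.per.sample = 32, reduce = FALSE)
  } else stop("bits must be 8, 16 or 32")
  invisible(path)
}

#' Field-of-view area in square millimeters
#'
#' For the standard 2048 x 400 px field at 0.325 um/px this gives
#' 0.0865 mm^2 (approximately 0.086 mm^2).
#'
#' @param width_px,height_px Field dimensions in pixels (> 0).
#' @param pixel_size_um Pixel edge length in micrometers (> 0).
#' @return Area in mm^2.
#' @export
fov_area_mm2 <- function(width_px, height_px, pixel_size_um) {
  if (any(c(width_px, height_px, pixel_size_um) <= 0)) {
    stop("all arguments must be positive")
  }
  width_px * height_px * pixel_size_um^2 / 1e6
}

#' Area of a circular coverslip in square millimeters
#' @param diameter_mm Coverslip diameter in millimeters (default the common
#'   12 mm coverslip, area ~113 mm^2).
#' @return Area in mm^2.
#' @export
coverslip_area_mm2 <- function(diameter_mm = 12) {
  if (diameter_mm <= 0) stop("diameter must be positive")
  pi * (diameter_mm / 2)^2
}

#' Percentage of a culture area lying outside one field of view
#'
#' Quantifies how little of a bulk coverslip culture a single camera field
#' samples; for a 12 mm coverslip and the standard field this exceeds 99.9%.
#'
#' @param fov_mm2 Imaged area (mm^2).
#' @param total_mm2 Total culture area (mm^2), must be >= `fov_mm2`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_outside_fov <- function(fov_mm2, total_mm2) {
  if (fov_mm2 < 0 || total_mm2 <= 0 || total_mm2 < fov_mm2) {
    stop("need 0 <= fov_mm2 <= total_mm2")
  }
  100 * (total_mm2 - fov_mm2) / total_mm2
}

#' One imaged area: brightfield image plus ordered fluorescence movies
#' @param area_id Identifier (usually `<coverslip>/<area>`).
#' @param brightfield_path Path to the single-frame brightfield TIFF.
#' @param movie_paths Character vector of movie paths in epoch order.
#' @param frame_period_ms Frame period shared by all epochs.
#' @return A `recording_area` object.
#' @export
recording_area <- function(area_id, brightfield_path, movie_paths,
                           frame_period_ms = 2) {
  if (length(movie_paths) < 1) stop("an area needs at least one movie")
  structure(list(area_id = area_id, brightfield_path = brightfield_path,
                 movie_paths = movie_paths,
                 frame_period_ms = frame_period_ms),
            class = "recording_area")
}

#' Scan a coverslip/area directory tree
#'
#' The on-disk layout mirrors the acquisition bookkeeping: the root holds one
#' folder per coverslip, each holding one folder per imaged area. An area
#' folder contains a single brightfield TIFF (filename containing
#' "brightfield", case-insensitive) and the fluorescence movies as further
#' TIFFs. TIFFs whose name contains "mask" are ROI geometry written by
#' [write_rois()], not movies, and are ignored. Movies are ordered by
#' filename, which encodes the recording sequence. Areas without a
#' brightfield image are skipped with a warning.
#'
#' @param root_dir Dataset root.
#' @param frame_period_ms Frame period attached to every area.
#' @return List of `recording_area`, ordered by coverslip then area name.
#' @export
scan_dataset <- function(root_dir, frame_period_ms = 2) {
  if (!dir.exists(root_dir)) stop("no such directory: ", root_dir)
  coverslips <- sort(list.dirs(root_dir, recursive = FALSE))
  if (!length(coverslips)) {
    warning("empty dataset root: ", root_dir)
    return(list())
  }
  areas <- list()
  for (cs in coverslips) {
    for (ar in sort(list.dirs(cs, recursive = FALSE))) {
      tifs <- sort(list.files(ar, pattern = "\\.tiff?$", ignore.case = TRUE,
                              full.names = TRUE))
      bf <- tifs[grepl("brightfield", basename(tifs), ignore.case = TRUE)]
      masks <- tifs[grepl("mask", basename(tifs), ignore.case = TRUE)]
      movies <- setdiff(tifs, c(bf, masks))
      area_id <- file.path(basename(cs), basename(ar))
      if (!length(bf)) {
        warning("area ", area_id, " has no brightfield image; skipped")
        next
      }
      if (!length(movies)) {
        warning("area ", area_id, " has no movies; skipped")
        next
      }
      areas[[length(areas) + 1]] <-
        recording_area(area_id, bf[1], movies, frame_period_ms)
    }
  }
  areas
}
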