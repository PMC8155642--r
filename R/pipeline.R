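#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Each area folder in the
#' dataset is expected to contain its movies and brightfield TIFF, an ROI
#' file `rois.json` (schema of [write_rois()]), and optionally a marker
#' table `markers.csv` for cell typing.
#'
#' @param root Dataset root directory (coverslip/area layout).
#' @param out_dir Output directory; one subdirectory per area is created.
#' @param frame_period_ms Frame period (ms).
#' @param detection A [detection_config()].
#' @param sttc_dt_ms STTC coincidence half-window (ms).
#' @param window A [lag_window()] for XCI.
#' @param max_lag_ms Lag-histogram range (ms).
#' @param baseline_mode dF/F baseline mode; see [compute_dff()].
#' @param seed Seed recorded in the manifest and passed to detection.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(root, out_dir, frame_period_ms = 2,
                            detection = detection_config(),
                            sttc_dt_ms = 10, window = lag_window(),
                            max_lag_ms = 50,
                            baseline_mode = "leading_frames", seed = 1L) {
  structure(list(root = root, out_dir = out_dir,
                 frame_period_ms = frame_period_ms, detection = detection,
                 sttc_dt_ms = sttc_dt_ms, window = window,
                 max_lag_ms = max_lag_ms, baseline_mode = baseline_mode,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()] with the
#' detection block flattened: `root, out_dir, frame_period_ms,
#' snr_threshold, kmeans_restarts, min_separation_frames, sttc_dt_ms,
#' lag_low_ms, lag_high_ms, max_lag_ms, baseline_mode, seed`. Missing keys
#' keep their defaults.
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  det <- detection_config(
    snr_threshold = y$snr_threshold %||% 4,
    kmeans_restarts = y$kmeans_restarts %||% 10,
    rng_seed = y$seed %||% 1L,
    min_separation_frames = y$min_separation_frames %||% 3L)
  pipeline_config(
    root = y$root, out_dir = y$out_dir,
    frame_period_ms = y$frame_period_ms %||% 2,
    detection = det,
    sttc_dt_ms = y$sttc_dt_ms %||% 10,
    window = lag_window(y$lag_low_ms %||% 8, y$lag_high_ms %||% 14),
    max_lag_ms = y$max_lag_ms %||% 50,
    baseline_mode = y$baseline_mode %||% "leading_frames",
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyze one recording area
#'
#' Movies -> background-corrected traces -> dF/F -> spike trains -> metrics,
#' STTC, lag histograms, XCI and (when a marker table is present) the
#' cell-type-resolved XCI summary. All outputs are CSV files under
#' `out_dir`, plus a JSON manifest with the configuration echo and file
#' checksums.
#'
#' @param area A [recording_area()].
#' @param config A [pipeline_config()].
#' @return Invisible list of output paths.
#' @export
run_area <- function(area, config) {
  area_dir <- dirname(area$brightfield_path)
  rs <- read_rois(file.path(area_dir, "rois.json"))
  marker_path <- file.path(area_dir, "markers.csv")
  out <- file.path(config$out_dir, gsub("[/\\\\]", "_", area$area_id))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  movies <- lapply(seq_along(area$movie_paths), function(e) {
    load_movie(area$movie_paths[e], config$frame_period_ms, epoch_id = e)
  })
  raw <- lapply(movies, extract_traces, rs = rs)
  ids <- colnames(raw[[1]])
  dff <- lapply(ids, function(id) {
    compute_dff(lapply(raw, function(m) m[, id]),
                baseline_mode = config$baseline_mode)
  })
  trains <- lapply(seq_along(ids), function(i) {
    detect_spikes(dff[[i]], config$detection, config$frame_period_ms,
                  roi_id = ids[i])
  })
  if (file.exists(marker_path)) {
    trains <- label_trains(trains, read_marker_table(marker_path))
  }

  write_trace_csv(raw, file.path(out, "traces.csv"), config$frame_period_ms)
  write_spike_csv(trains, file.path(out, "spikes.csv"),
                  config = list(snr_threshold = config$detection$snr_threshold,
                                seed = config$seed))
  export_metrics(trains, file.path(out, "metrics.csv"))
  if (length(trains) >= 2) {
    st <- pairwise_sttc(trains, config$sttc_dt_ms)
    utils::write.csv(st$table, file.path(out, "sttc.csv"), row.names = FALSE)
    xm <- xci_matrix(trains, config$window, island_id = area$area_id)
    utils::write.csv(xm$table, file.path(out, "xci.csv"), row.names = FALSE)
    lh <- lag_histogram(trains, config$max_lag_ms, config$frame_period_ms)
    utils::write.csv(
      data.frame(bin_low_ms = lh$breaks[-length(lh$breaks)],
                 bin_high_ms = lh$breaks[-1], count = lh$pooled),
      file.path(out, "lag_hist.csv"), row.names = FALSE)
    if (file.exists(marker_path)) {
      utils::write.csv(celltype_xci_summary(xm$table),
                       file.path(out, "celltype_map.csv"), row.names = FALSE)
    }
  }
  files <- list.files(out, full.names = TRUE)
  manifest <- list(
    area_id = area$area_id,
    package_version = as.character(utils::packageVersion("voltconn")),
    seed = config$seed,
    config = list(frame_period_ms = config$frame_period_ms,
                  snr_threshold = config$detection$snr_threshold,
                  sttc_dt_ms = config$sttc_dt_ms,
                  lag_window = c(config$window$low_ms, config$window$high_ms),
                  baseline_mode = config$baseline_mode),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, file.path(out, "manifest.json")))
}

#' Run the full pipeline over a dataset
#'
#' Scans the coverslip/area tree and analyzes each area independently. A
#' failing area is logged and skipped; the remaining areas still complete.
#'
#' @param config A [pipeline_config()].
#' @return List with `ok` (area ids analyzed), `failed` (named character
#'   vector of error messages), and `n_areas`.
#' @export
run_pipeline <- function(config) {
  areas <- scan_dataset(config$root, config$frame_period_ms)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- character()
  failed <- character()
  for (a in areas) {
    res <- tryCatch({
      run_area(a, config)
      ok <- c(ok, a$area_id)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      warning("area ", a$area_id, " failed: ", res)
      failed[a$area_id] <- res
    }
  }
  list(ok = ok, failed = failed, n_areas = length(areas))
}
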