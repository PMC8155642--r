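#' Region of interest over one neuron soma or the background
#'
#' Geometry is either a polygon (two-column matrix of (col, row) vertices in
#' 0-based pixel units; the vertex (0, 0) is the outer corner of the top-left
#' pixel) or a logical mask the size of the imaging frame. A pixel belongs to
#' a polygon ROI when its center falls inside under the even-odd rule; pixel
#' (row r, col c), 0-based, has its center at (c + 0.5, r + 0.5).
#'
#' @param roi_id Character identifier, unique within its ROI set.
#' @param kind `"neuron"` or `"background"`.
#' @param polygon Optional n x 2 numeric matrix of (col, row) vertices.
#' @param mask Optional logical matrix (rows x cols) with at least one TRUE.
#' @param cell_type Cell-type label; see [cell_types()].
#' @return An object of class `roi`.
#' @export
roi <- function(roi_id, kind = c("neuron", "background"),
                polygon = NULL, mask = NULL, cell_type = "unknown") {
  kind <- match.arg(kind)
  cell_type <- match.arg(cell_type, cell_types())
  if (is.null(polygon) == is.null(mask)) {
    stop("supply exactly one of polygon or mask")
  }
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    if (ncol(polygon) != 2 || nrow(polygon) < 3) {
      stop("polygon needs >= 3 (col, row) vertices")
    }
    # drop an explicit closing vertex; closure is implicit
    if (all(polygon[1, ] == polygon[nrow(polygon), ]) && nrow(polygon) > 3) {
      polygon <- polygon[-nrow(polygon), , drop = FALSE]
    }
  }
  if (!is.null(mask)) {
    mask <- mask != 0
    if (!any(mask)) stop("mask must contain at least one pixel")
  }
  structure(list(roi_id = as.character(roi_id), kind = kind,
                 polygon = polygon, mask = mask, cell_type = cell_type),
            class = "roi")
}

#' Rasterize an ROI to a logical mask
#'
#' @param x An `roi`.
#' @param dim_hw Frame dimensions `c(rows, cols)`.
#' @return Logical rows x cols matrix.
#' @export
roi_mask <- function(x, dim_hw) {
  h <- dim_hw[1]; w <- dim_hw[2]
  if (!is.null(x$mask)) {
    if (!all(dim(x$mask) == c(h, w))) {
      stop("mask of ROI ", x$roi_id, " does not match frame size")
    }
    return(x$mask)
  }
  cx <- rep(seq_len(w) - 0.5, each = h)   # pixel-center x (col), 0-based units
  cy <- rep(seq_len(h) - 0.5, times = w)  # pixel-center y (row)
  inside <- point_in_polygon(cx, cy, x$polygon)
  m <- matrix(inside, nrow = h, ncol = w)
  if (!any(m)) stop("ROI ", x$roi_id, " rasterizes to an empty mask")
  m
}

# Even-odd ray casting, vectorized over query points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[j[i]]; y2 <- ys[j[i]]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

#' Set of ROIs for one imaged area
#'
#' Exactly one background ROI is required: spike detection subtracts the
#' frame-wise background mean from every neuron trace.
#'
#' @param area_id Area identifier.
#' @param rois List of [roi()] objects with unique ids, at least one of kind
#'   `"neuron"` and exactly one of kind `"background"`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(area_id, rois) {
  kinds <- vapply(rois, function(r) r$kind, "")
  ids <- vapply(rois, function(r) r$roi_id, "")
  if (anyDuplicated(ids)) stop("duplicate roi_id in ROI set")
  if (sum(kinds == "background") != 1) {
    stop("an ROI set requires exactly one background ROI")
  }
  if (sum(kinds == "neuron") < 1) stop("an ROI set requires >= 1 neuron ROI")
  structure(list(area_id = as.character(area_id),
                 neurons = rois[kinds == "neuron"],
                 background = rois[kinds == "background"][[1]]),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %s: %d neuron ROI(s) + background\n",
              x$area_id, length(x$neurons)))
  invisible(x)
}

all_rois <- function(rs) c(rs$neurons, list(rs$background))

#' Write an ROI set to JSON
#'
#' Schema: `{"area_id": str, "rois": [{"id", "kind", "polygon" | "mask_path",
#' "cell_type"}]}`. Mask geometries are written as single-frame 8-bit TIFFs
#' next to the JSON file and referenced by relative `mask_path`.
#'
#' @param rs An `roi_set`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rs, path) {
  stopifnot(inherits(rs, "roi_set"))
  dir <- dirname(path)
  entries <- lapply(all_rois(rs), function(r) {
    e <- list(id = r$roi_id, kind = r$kind, cell_type = r$cell_type)
    if (!is.null(r$polygon)) {
      e$polygon <- unname(apply(r$polygon, 1, function(v) v, simplify = FALSE))
    } else {
      mp <- paste0(tools::file_path_sans_ext(basename(path)), "_",
                   gsub("[^A-Za-z0-9_.-]", "_", r$roi_id), "_mask.tif")
      tiff::writeTIFF(r$mask * 1.0, file.path(dir, mp), bits.per.sample = 8)
      e$mask_path <- mp
    }
    e
  })
  jsonlite::write_json(list(area_id = rs$area_id, rois = entries), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI set from JSON written by [write_rois()]
#' @param path JSON path.
#' @return An `roi_set`.
#' @export
read_rois <- function(path) {
  doc <- jsonlite::read_json(path)
  rois <- lapply(doc$rois, function(e) {
    if (!is.null(e$polygon)) {
      poly <- do.call(rbind, lapply(e$polygon, unlist))
      roi(e$id, e$kind, polygon = poly, cell_type = e$cell_type)
    } else {
      m <- tiff::readTIFF(file.path(dirname(path), e$mask_path), as.is = TRUE)
      roi(e$id, e$kind, mask = m > 0, cell_type = e$cell_type)
    }
  })
  roi_set(doc$area_id, rois)
}

#' Write then re-read an ROI set
#'
#' Round-trip used by the pipeline to persist manually drawn ROIs; the result
#' is identical to the input in geometry, kinds and labels.
#'
#' @param rs An `roi_set`.
#' @param path JSON path.
#' @return The re-read `roi_set`.
#' @export
roundtrip_rois <- function(rs, path) {
  write_rois(rs, path)
  read_rois(path)
}
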