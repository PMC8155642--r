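#' Assign a hippocampal cell type from immunomarker presence
#'
#' Decision table over four markers, applied in precedence order:
#' GAD67 present -> inhibitory (unconditionally, regardless of co-staining);
#' else CaMKII and Prox1 -> dentate granule cell; else CaMKII and CTIP2 ->
#' CA1; else CaMKII alone -> CA3; else unknown. Prox1 is checked before
#' CTIP2, so a triple-positive CaMKII/Prox1/CTIP2 profile reads as DGC
#' (CA1 calls require Prox1-negative staining).
#'
#' All arguments are recycled logical vectors, so the function works on
#' whole marker tables at once.
#'
#' @param camkii,gad67,ctip2,prox1 Logical marker presence.
#' @return Character vector of labels among [cell_types()].
#' @export
assign_cell_type <- function(camkii, gad67, ctip2, prox1) {
  n <- max(length(camkii), length(gad67), length(ctip2), length(prox1))
  camkii <- rep_len(as.logical(camkii), n)
  gad67 <- rep_len(as.logical(gad67), n)
  ctip2 <- rep_len(as.logical(ctip2), n)
  prox1 <- rep_len(as.logical(prox1), n)
  ifelse(gad67, "inhibitory",
    ifelse(camkii & prox1, "DGC",
      ifelse(camkii & ctip2, "CA1",
        ifelse(camkii, "CA3", "unknown"))))
}

#' Read a marker table and assign cell types
#'
#' Input CSV columns: `roi_id, camkii, gad67, ctip2, prox1` (0/1 or
#' TRUE/FALSE).
#'
#' @param path Marker CSV path.
#' @return Data frame `roi_id, cell_type`.
#' @export
read_marker_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "camkii", "gad67", "ctip2", "prox1")
  if (!all(need %in% names(df))) {
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  }
  data.frame(roi_id = df$roi_id,
             cell_type = assign_cell_type(parse_flag(df$camkii),
                                          parse_flag(df$gad67),
                                          parse_flag(df$ctip2),
                                          parse_flag(df$prox1)))
}

# 0/1 and TRUE/FALSE encodings, possibly mixed within one column (read.csv
# then delivers character), all map to logical; anything else is an error.
parse_flag <- function(v) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) {
    if (any(!v %in% c(0, 1))) stop("marker flags must be 0/1 or TRUE/FALSE")
    return(v == 1)
  }
  v <- trimws(as.character(v))
  yes <- v %in% c("1", "TRUE", "true", "T")
  no <- v %in% c("0", "FALSE", "false", "F")
  if (any(!(yes | no))) stop("marker flags must be 0/1 or TRUE/FALSE")
  yes
}

#' Threshold mean ROI channel intensities into marker presence
#'
#' Convenience helper for semi-automated scoring: a marker is called present
#' when the mean ROI intensity in that channel is at least `k` times the
#' background-ROI mean. Manual scoring remains the reference; this helper
#' carries no fidelity claim.
#'
#' @param roi_means Numeric matrix, ROIs x channels.
#' @param background_means Numeric vector of background means per channel.
#' @param k Fold-over-background threshold (default 2).
#' @return Logical matrix of the same shape.
#' @export
threshold_markers <- function(roi_means, background_means, k = 2) {
  stopifnot(ncol(roi_means) == length(background_means), k > 0)
  sweep(roi_means, 2, k * background_means, `>=`)
}

#' Attach cell-type labels to spike trains
#' @param trains List of [spike_train()] objects.
#' @param labels Data frame `roi_id, cell_type` (e.g. from
#'   [read_marker_table()]); ROIs absent from it stay `"unknown"`.
#' @return The trains with updated `cell_type` fields.
#' @export
label_trains <- function(trains, labels) {
  lapply(trains, function(tr) {
    hit <- match(tr$roi_id, labels$roi_id)
    if (!is.na(hit)) tr$cell_type <- labels$cell_type[hit]
    tr
  })
}
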