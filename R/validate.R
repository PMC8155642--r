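#' Agreement between a ground-truth and a detected spike train
#'
#' Greedy one-to-one matching per epoch: each true spike claims the earliest
#' unclaimed detected spike within `tol_ms`. Sensitivity is matched true
#' spikes over all true spikes; precision is matched detected spikes over
#' all detected spikes. The default 2 ms tolerance is one frame at 500 Hz,
#' the temporal resolution of optical detection.
#'
#' @param truth,detected [spike_train()] objects with the same epoch
#'   structure.
#' @param tol_ms Matching tolerance (ms).
#' @return List: `tp`, `n_true`, `n_detected`, `sensitivity`, `precision`,
#'   `f1`, `max_timing_error_ms` (largest |error| among matches, NA if
#'   none).
#' @export
spike_train_agreement <- function(truth, detected, tol_ms = 2) {
  stopifnot(length(truth$times) == length(detected$times))
  tp <- 0L
  errs <- numeric(0)
  for (e in seq_along(truth$times)) {
    tt <- truth$times[[e]]
    dd <- detected$times[[e]]
    used <- rep(FALSE, length(dd))
    for (t in tt) {
      i <- which(!used & abs(dd - t) <= tol_ms)
      if (length(i)) {
        used[i[1]] <- TRUE
        tp <- tp + 1L
        errs <- c(errs, abs(dd[i[1]] - t))
      }
    }
  }
  nt <- n_spikes(truth)
  nd <- n_spikes(detected)
  sens <- if (nt) tp / nt else NA_real_
  prec <- if (nd) tp / nd else NA_real_
  list(tp = tp, n_true = nt, n_detected = nd,
       sensitivity = sens, precision = prec,
       f1 = if (!is.na(sens) && !is.na(prec) && sens + prec > 0) {
         2 * sens * prec / (sens + prec)
       } else NA_real_,
       max_timing_error_ms = if (length(errs)) max(errs) else NA_real_)
}
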