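# End-to-end plumbing: records -> labelled training windows, and
# record + model -> detected beats -> metrics.

#' Prepare labelled training windows from a record
#'
#' Band-pass filters the record, cuts non-overlapping 10 s windows, builds
#' the 0/1 QRS target at the native rate, then downsamples the signals and
#' stride-decimates the targets with the same factor, so signal and target
#' stay aligned at the scaled resolution.
#'
#' @param record An [ecg_record()].
#' @param factor Scaling factor (default 0.2).
#' @param window_s Window length in seconds (default 10).
#' @param band Band-pass edges in Hz (default `c(1, 40)`).
#' @return List of windows, each `list(x = H x Ws x 1 array, mask =
#'   length-Ws 0/1 vector, offset, fs)`.
#' @export
prepare_training_windows <- function(record, factor = 0.2, window_s = 10,
                                     band = c(1, 40)) {
  rec <- filter_record(record, band[1], band[2])
  wins <- segment_windows(rec, window_s = window_s)
  lapply(wins, function(w) {
    mask <- make_mask(w$r_peaks_local, ncol(w$signals), w$fs)
    list(x = axis_transform(downsample(w$signals, factor)),
         mask = decimate_mask(mask, factor),
         r_peaks = w$r_peaks_local,
         offset = w$offset, fs = w$fs)
  })
}

#' Detect QRS complexes in a record
#'
#' The full inference path: band-pass filter, 10 s windowing (the trailing
#' partial window is zero-padded and trimmed again), stride decimation by
#' the scaling factor, leads distillation, U-Net segmentation,
#' nearest-value upsampling of the probabilities back to the native rate,
#' binarization and region-to-peak conversion.
#'
#' @param model A trained `qrs_detector`.
#' @param record An [ecg_record()] (its `r_peaks`, if any, are ignored).
#' @param factor Scaling factor (default from the model's train config).
#' @param threshold Binarization threshold (default from the model config).
#' @param min_qrs_ms Minimum detected-region width in ms (default from the
#'   model config).
#' @param window_s Window length in seconds (default 10).
#' @return Sorted integer vector of detected R-peak indices (0-based), with
#'   the per-sample probability sequence attached as attribute
#'   `"probability"`.
#' @export
detect_record <- function(model, record, factor = NULL, threshold = NULL,
                          min_qrs_ms = NULL, window_s = 10) {
  stopifnot(inherits(model, "qrs_detector"), inherits(record, "ecg_record"))
  factor <- factor %||% model$cfg$train$scaling_factor
  threshold <- threshold %||% model$cfg$threshold
  min_qrs_ms <- min_qrs_ms %||% model$cfg$min_qrs_ms
  band <- model$cfg$band
  rec <- filter_record(record, band[1], band[2])
  wins <- segment_windows(rec, window_s = window_s, pad_tail = TRUE)
  H <- nrow(rec$signals)
  n <- ncol(rec$signals)
  prob <- numeric(n)
  xs <- lapply(wins, function(w) downsample(w$signals, factor))
  ws <- ncol(xs[[1]])
  B <- length(xs)
  x <- array(0, c(B * H, ws, 1L))
  for (b in seq_len(B))
    x[(b - 1L) * H + seq_len(H), , 1L] <- xs[[b]]
  lf <- ldm_forward_batch(x, model$params, model$stats, H = H, B = B,
                          training = FALSE, slope = model$cfg$ldm$lrelu_slope)
  uf <- unet_forward_batch(lf$out, model$params, lf$stats, model$cfg$unet,
                           training = FALSE, slope = model$cfg$ldm$lrelu_slope)
  for (b in seq_len(B)) {
    w <- wins[[b]]
    up <- upsample_prediction(uf$out[b, ], factor, ncol(w$signals))
    take <- seq_len(w$n_valid)
    prob[w$offset + take] <- up[take]
  }
  peaks <- mask_to_peaks(binarize(prob, threshold), rec$fs, min_qrs_ms)
  attr(peaks, "probability") <- prob
  peaks
}

#' Evaluate a detector on a set of records
#'
#' Runs [detect_record()] on every record, matches detections to the
#' reference beats with the AAMI rule and reports per-record and pooled
#' (gross: counts summed before dividing) metrics.
#'
#' @param model A trained `qrs_detector`.
#' @param records List of [ecg_record()]s with reference `r_peaks`.
#' @param ... Passed to [detect_record()].
#' @return A [tibble::tibble] with one row per record plus a final
#'   `"pooled"` row; columns `record`, `TP`, `FP`, `FN`, `Se`, `PPv`, `F1`,
#'   `defined`.
#' @export
evaluate_detector <- function(model, records, ...) {
  rows <- list()
  tot <- list(TP = 0L, FP = 0L, FN = 0L)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    det <- detect_record(model, rec, ...)
    m <- match_beats(as.integer(det), rec$r_peaks, rec$fs,
                     tol_ms = model$cfg$match_tol_ms)
    tot$TP <- tot$TP + m$TP
    tot$FP <- tot$FP + m$FP
    tot$FN <- tot$FN + m$FN
    rows[[i]] <- cbind(tibble::tibble(record = as.character(i)),
                       compute_metrics(m))
  }
  pooled <- cbind(tibble::tibble(record = "pooled"), compute_metrics(tot))
  do.call(rbind, c(rows, list(pooled)))
}

#' Evaluate windows already at the scaled resolution
#'
#' Desk-scale evaluation used by the training experiments: each held-out
#' window (as produced by [prepare_training_windows()], with known R-peaks
#' at the native rate) is segmented by the model, upsampled, binarized and
#' matched. Returns pooled counts and metrics.
#'
#' @param model A trained `qrs_detector`.
#' @param windows List of windows with `x`, `fs` and native-rate reference
#'   peaks in `r_peaks`.
#' @param factor Scaling factor used to build the windows.
#' @return One-row tibble of pooled metrics.
#' @export
evaluate_windows <- function(model, windows, factor = NULL) {
  factor <- factor %||% model$cfg$train$scaling_factor
  H <- dim(windows[[1]]$x)[1]
  ws <- dim(windows[[1]]$x)[2]
  B <- length(windows)
  x <- array(0, c(B * H, ws, 1L))
  for (b in seq_len(B))
    x[(b - 1L) * H + seq_len(H), , 1L] <- windows[[b]]$x[, , 1L]
  lf <- ldm_forward_batch(x, model$params, model$stats, H = H, B = B,
                          training = FALSE, slope = model$cfg$ldm$lrelu_slope)
  uf <- unet_forward_batch(lf$out, model$params, lf$stats, model$cfg$unet,
                           training = FALSE, slope = model$cfg$ldm$lrelu_slope)
  tot <- list(TP = 0L, FP = 0L, FN = 0L)
  for (b in seq_len(B)) {
    w <- windows[[b]]
    native_len <- round(ws / factor)
    up <- upsample_prediction(uf$out[b, ], factor, native_len)
    det <- mask_to_peaks(binarize(up, model$cfg$threshold), w$fs,
                         model$cfg$min_qrs_ms)
    m <- match_beats(as.integer(det), w$r_peaks, w$fs,
                     tol_ms = model$cfg$match_tol_ms)
    tot$TP <- tot$TP + m$TP
    tot$FP <- tot$FP + m$FP
    tot$FN <- tot$FN + m$FN
  }
  compute_metrics(tot)
}
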