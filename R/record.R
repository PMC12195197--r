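#' Multi-lead ECG record
#'
#' Container for a multi-lead ECG: a leads-by-samples amplitude matrix (mV),
#' the sampling frequency, ordered lead names, and the annotated R-peak
#' positions as 0-based sample indices.
#'
#' @param signals Numeric matrix, one row per lead, one column per sample,
#'   amplitudes in mV. A vector is treated as a single lead.
#' @param fs Sampling frequency in Hz (positive scalar).
#' @param lead_names Character vector of lead identifiers, one per row of
#'   `signals`. Defaults to `"L1"`, `"L2"`, ...
#' @param r_peaks Strictly increasing integer vector of 0-based sample
#'   indices of annotated R-peaks, all within `[0, ncol(signals))`.
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signals, fs, lead_names = NULL, r_peaks = integer()) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  stopifnot(is.matrix(signals), is.numeric(signals))
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  n <- ncol(signals)
  if (is.null(lead_names)) lead_names <- paste0("L", seq_len(nrow(signals)))
  if (length(lead_names) != nrow(signals))
    stop("`lead_names` must have one entry per lead")
  r_peaks <- as.integer(round(r_peaks))
  if (length(r_peaks)) {
    if (any(r_peaks < 0L) || any(r_peaks >= n))
      stop("r_peaks must lie in [0, samples)")
    if (any(diff(r_peaks) <= 0L))
      stop("r_peaks must be strictly increasing")
  }
  rownames(signals) <- lead_names
  structure(
    list(signals = signals, fs = fs, lead_names = lead_names,
         r_peaks = r_peaks),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> %d lead(s) x %d samples @ %g Hz (%.1f s), %d annotated beats\n",
    nrow(x$signals), ncol(x$signals), x$fs, ncol(x$signals) / x$fs,
    length(x$r_peaks)))
  cat("  leads:", paste(x$lead_names, collapse = ", "), "\n")
  invisible(x)
}

#' Cut a record into fixed-duration windows
#'
#' Splits a record into consecutive windows of `window_s` seconds. The
#' default stride equals the window length, giving a non-overlapping cover;
#' the trailing remainder shorter than a full window is dropped unless
#' `pad_tail = TRUE`, in which case it is zero-padded to full length and its
#' true length recorded (inference mode; the padding is trimmed again by
#' [detect_record()]).
#'
#' Windows use half-open 0-based sample coordinates `[offset, offset + W)`;
#' each window carries the R-peaks that fall inside it, re-based to the
#' window start.
#'
#' @param record An [ecg_record()].
#' @param window_s Window length in seconds (default 10).
#' @param stride_s Stride between window starts in seconds (default
#'   `window_s`, i.e. non-overlapping).
#' @param pad_tail Keep the trailing partial window, zero-padded?
#' @return List of `ecg_window` objects with fields `signals` (leads x W),
#'   `fs`, `offset` (0-based start sample), `r_peaks_local` and `n_valid`
#'   (number of real, un-padded samples).
#' @export
segment_windows <- function(record, window_s = 10, stride_s = window_s,
                            pad_tail = FALSE) {
  stopifnot(inherits(record, "ecg_record"), window_s > 0, stride_s > 0)
  w <- round(window_s * record$fs)
  stride <- round(stride_s * record$fs)
  n <- ncol(record$signals)
  if (n < w && !pad_tail) stop("record shorter than one window")
  starts <- seq(0L, max(0L, n - 1L), by = stride)
  windows <- list()
  for (off in starts) {
    n_valid <- min(w, n - off)
    if (n_valid <= 0L) break
    if (n_valid < w && !pad_tail) break
    sig <- matrix(0, nrow = nrow(record$signals), ncol = w)
    sig[, seq_len(n_valid)] <- record$signals[, off + seq_len(n_valid), drop = FALSE]
    rownames(sig) <- record$lead_names
    rp <- record$r_peaks[record$r_peaks >= off & record$r_peaks < off + n_valid]
    windows[[length(windows) + 1L]] <- structure(
      list(signals = sig, fs = record$fs, offset = off,
           r_peaks_local = rp - off, n_valid = n_valid),
      class = "ecg_window")
  }
  windows
}

#' Reshape a leads-by-samples matrix into an H x W x 1 feature map
#'
#' The "axis transform": an L-lead, W-sample window becomes a single-channel
#' image with height L and width W, so that one convolutional architecture
#' (whose kernels all have height 1) serves any lead count. Row `i` of the
#' map is lead `i`, unchanged.
#'
#' @param window_signals Numeric leads x W matrix (or vector for one lead).
#' @return Numeric array with dim `c(H, W, 1)`.
#' @seealso [axis_untransform()]
#' @export
axis_transform <- function(window_signals) {
  if (is.vector(window_signals)) window_signals <- matrix(window_signals, nrow = 1)
  stopifnot(is.matrix(window_signals))
  if (length(window_signals) == 0) stop("empty signal matrix")
  array(window_signals, dim = c(nrow(window_signals), ncol(window_signals), 1L))
}

#' Invert the axis transform
#'
#' @param x Array of dim `c(H, W, 1)`.
#' @return The H x W matrix.
#' @export
axis_untransform <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[3] == 1)
  matrix(x, nrow = dim(x)[1], ncol = dim(x)[2])
}
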