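#' Zero-phase 1-40 Hz band-pass filter
#'
#' Removes baseline wander (below 1 Hz) and high-frequency noise (above
#' 40 Hz) before windowing and scaling. Realized as a 4th-order Butterworth
#' band-pass applied forward and backward ([signal::filtfilt()]), so the
#' filter is zero-phase and beat positions are not shifted relative to the
#' annotations.
#'
#' @param x Numeric vector, one lead's amplitude sequence.
#' @param fs Sampling frequency in Hz; must exceed twice the upper band
#'   edge (i.e. `fs > 80` for the default band).
#' @param low,high Pass-band edges in Hz (defaults 1 and 40).
#' @param order Butterworth order per pass (default 4).
#' @return Filtered vector, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 1, high = 40, order = 4) {
  stopifnot(is.numeric(x), length(x) > 0)
  if (fs <= 2 * high)
    stop(sprintf("fs = %g Hz: upper band edge %g Hz at or above Nyquist", fs, high))
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # removing the mean first shrinks the start-up transients of the
  # forward-backward pass; DC is outside the pass band regardless
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Band-pass filter every lead of a record
#'
#' @param record An [ecg_record()].
#' @inheritParams bandpass_filter
#' @return The record with filtered signals; annotations unchanged.
#' @export
filter_record <- function(record, low = 1, high = 40, order = 4) {
  stopifnot(inherits(record, "ecg_record"))
  record$signals <- t(apply(record$signals, 1, bandpass_filter,
                            fs = record$fs, low = low, high = high,
                            order = order))
  rownames(record$signals) <- record$lead_names
  record
}

check_scaling_factor <- function(factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1)
    stop("scaling factor must lie in (0, 1]")
  stride <- 1 / factor
  if (abs(stride - round(stride)) > 1e-8)
    stop("1/factor must be a positive integer (admissible scaling factors)")
  as.integer(round(stride))
}

#' Downsample a signal by a scaling factor
#'
#' The down half of the scaling operation: plain stride decimation keeping
#' every (1/factor)-th sample starting at index 0, with no anti-alias
#' prefilter. The admissible factors are those whose reciprocal is a whole
#' number; the output has `floor(N * factor)` samples (a trailing partial
#' stride block is dropped).
#'
#' @param x Numeric vector, or a leads x N matrix (decimated along columns).
#' @param factor Scaling factor in (0, 1] with integer reciprocal, e.g. 0.2.
#' @return Decimated vector or matrix.
#' @export
downsample <- function(x, factor) {
  stride <- check_scaling_factor(factor)
  n <- if (is.matrix(x)) ncol(x) else length(x)
  keep <- seq.int(1L, by = stride, length.out = n %/% stride + (n %% stride > 0))
  keep <- keep[seq_len(floor(n * factor))]
  if (is.matrix(x)) x[, keep, drop = FALSE] else x[keep]
}

#' Nearest-value (zero-order-hold) upsampling
#'
#' The up half of the scaling operation: each sample is repeated `times`
#' consecutive positions.
#'
#' @param x Numeric vector.
#' @param times Positive integer repetition count.
#' @return Vector of length `length(x) * times`.
#' @export
upsample_nearest <- function(x, times) {
  if (!is.numeric(times) || length(times) != 1 || times < 1 ||
      abs(times - round(times)) > 1e-8)
    stop("`times` must be a positive integer")
  rep(x, each = as.integer(round(times)))
}

#' Upsample a prediction back to the original resolution
#'
#' Applies nearest-value repetition by `1/factor` to a probability sequence
#' or binary mask produced at the scaled resolution, then crops to
#' `target_length` (the original window length) when given.
#'
#' @param x Numeric vector at scaled resolution.
#' @param factor The scaling factor used on the input signal.
#' @param target_length Optional original length to crop (or zero-pad) to.
#' @return Vector at original resolution.
#' @export
upsample_prediction <- function(x, factor, target_length = NULL) {
  stride <- check_scaling_factor(factor)
  y <- upsample_nearest(x, stride)
  if (!is.null(target_length)) {
    if (length(y) >= target_length) y <- y[seq_len(target_length)]
    else y <- c(y, rep(y[length(y)], target_length - length(y)))
  }
  y
}
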