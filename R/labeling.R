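#' Width of a QRS label in samples
#'
#' The per-sample binary target marks, around every annotated R-peak, a
#' symmetric window of about 150 ms (the AAMI-derived QRS label duration):
#' `floor(0.075 * fs)` samples on each side of the R sample, i.e. an odd
#' total width of `2 * floor(0.075 * fs) + 1`. This reproduces the standard
#' widths 39 @ 257 Hz, 55 @ 360 Hz and 75 @ 500 Hz.
#'
#' @param fs Sampling frequency in Hz.
#' @return Odd positive integer width in samples.
#' @export
label_width <- function(fs) {
  stopifnot(is.numeric(fs), length(fs) == 1, fs > 0)
  2L * as.integer(floor(0.075 * fs)) + 1L
}

#' Build a per-sample binary QRS mask from R-peak positions
#'
#' Each annotated peak `p` (0-based) sets positions
#' `[p - half, p + half]` to 1, where `half = (label_width(fs) - 1) / 2`;
#' labels overlapping the window edge are truncated, overlapping labels
#' merge, and all other positions stay 0.
#'
#' @param r_peaks Sorted 0-based sample indices of R-peaks.
#' @param length Number of samples in the mask.
#' @param fs Sampling frequency in Hz.
#' @return Integer vector of 0/1 values of the requested length.
#' @export
make_mask <- function(r_peaks, length, fs) {
  stopifnot(length >= 0)
  r_peaks <- as.integer(round(r_peaks))
  if (any(r_peaks < 0L) || any(r_peaks >= length))
    stop("r_peaks must lie in [0, length)")
  mask <- integer(length)
  half <- (label_width(fs) - 1L) %/% 2L
  for (p in r_peaks) {
    lo <- max(0L, p - half)
    hi <- min(length - 1L, p + half)
    mask[(lo + 1L):(hi + 1L)] <- 1L
  }
  mask
}

#' Decimate a binary mask to the scaled resolution
#'
#' Training targets are built at the native sampling frequency and then
#' stride-decimated with the same stride and phase as the signal, which
#' keeps signal and target aligned sample-for-sample at the scaled
#' resolution.
#'
#' @param mask Integer 0/1 vector.
#' @param factor Scaling factor, as in [downsample()].
#' @return Decimated 0/1 vector.
#' @export
decimate_mask <- function(mask, factor) {
  stopifnot(all(mask %in% c(0L, 1L)))
  as.integer(downsample(as.numeric(mask), factor))
}
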