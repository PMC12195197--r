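# From probability sequences to detected beats, and beat-by-beat
# evaluation with the AAMI matching rule.

#' Binarize a probability sequence
#'
#' @param p Numeric vector of probabilities.
#' @param threshold Decision threshold in (0, 1); values `>= threshold`
#'   become 1 (ties count as detections).
#' @return Integer 0/1 vector.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  as.integer(p >= threshold)
}

#' Convert a binary mask into detected R-peak positions
#'
#' Maximal runs of ones shorter than `min_width_ms` are discarded as
#' spurious; each surviving run yields one detection at its midpoint
#' (floor of the mean of the run endpoints, 0-based).
#'
#' @param mask Integer 0/1 vector at the original sampling rate.
#' @param fs Sampling frequency in Hz.
#' @param min_width_ms Minimum run width in milliseconds (default 40,
#'   about half the narrowest plausible QRS).
#' @return Sorted integer vector of 0-based detection indices.
#' @export
mask_to_peaks <- function(mask, fs, min_width_ms = 40) {
  stopifnot(all(mask %in% c(0L, 1L)))
  if (!any(mask > 0)) return(integer(0))
  r <- rle(as.integer(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values == 1L
  min_w <- fs * min_width_ms / 1000
  keep <- on & r$lengths >= min_w
  if (!any(keep)) return(integer(0))
  # 0-based run endpoints [s, e]; detection at floor((s + e) / 2)
  s0 <- starts[keep] - 1L
  e0 <- ends[keep] - 1L
  as.integer((s0 + e0) %/% 2L)
}

#' Match detected beats to reference beats (AAMI rule)
#'
#' A detection is a true positive when it lies within a region of
#' `tol_ms` milliseconds centered on a reference annotation (default 75 ms,
#' i.e. +/- 37.5 ms, a tolerance of `floor(0.0375 * fs)` samples, so a detection never lies
#' outside the literal region). Matching
#' is greedy, chronological and one-to-one: references are visited in
#' order, each taking the nearest unused detection within tolerance
#' (earlier detection on ties). Unmatched detections are false positives,
#' unmatched references false negatives.
#'
#' @param detected Sorted, deduplicated 0-based detection indices.
#' @param reference Sorted, deduplicated 0-based reference R-peak indices.
#' @param fs Sampling frequency in Hz.
#' @param tol_ms Width of the matching region in ms (default 75).
#' @return List of class `beat_match` with counts `TP`, `FP`, `FN` and a
#'   two-column matrix `pairs` of matched (detected, reference) indices.
#' @export
match_beats <- function(detected, reference, fs, tol_ms = 75) {
  if (is.unsorted(detected, strictly = TRUE) && length(detected) > 1)
    stop("`detected` must be sorted and deduplicated")
  if (is.unsorted(reference, strictly = TRUE) && length(reference) > 1)
    stop("`reference` must be sorted and deduplicated")
  tol <- floor(tol_ms / 2 / 1000 * fs)
  used <- logical(length(detected))
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("detected", "reference")))
  for (r in reference) {
    cand <- which(!used & abs(detected - r) <= tol)
    if (length(cand)) {
      d <- abs(detected[cand] - r)
      pick <- cand[which.min(d)]       # nearest; earlier detection on ties
      used[pick] <- TRUE
      pairs <- rbind(pairs, c(detected[pick], r))
    }
  }
  tp <- nrow(pairs)
  structure(list(TP = tp, FP = length(detected) - tp,
                 FN = length(reference) - tp, pairs = pairs),
            class = "beat_match")
}

#' Sensitivity, positive predictivity and F1 from match counts
#'
#' `Se = TP / (TP + FN) * 100`, `PPv = TP / (TP + FP) * 100`,
#' `F1 = 2 TP / (2 TP + FP + FN) * 100`. A metric with a zero denominator
#' is undefined and reported as `NA` with `defined = FALSE`. For pooled
#' ("gross") statistics over several records, sum the TP/FP/FN counts
#' before calling.
#'
#' @param result A `beat_match` from [match_beats()], or a list with
#'   elements `TP`, `FP`, `FN`.
#' @return A [tibble::tibble] with columns `TP`, `FP`, `FN`, `Se`, `PPv`,
#'   `F1` (percent / 0-100 scale) and `defined`.
#' @export
compute_metrics <- function(result) {
  tp <- result$TP; fp <- result$FP; fn <- result$FN
  se <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) * 100 else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) * 100 else NA_real_
  tibble::tibble(TP = tp, FP = fp, FN = fn, Se = se, PPv = ppv, F1 = f1,
                 defined = !anyNA(c(se, ppv, f1)))
}
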