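# Desk-scale analytic experiments: the scaling-factor x kernel-size scan
# and the frequency-domain account of why the scaling operation helps.

#' Admissible scaling factors
#'
#' Factors whose reciprocal is a whole number, down to the minimum 0.1.
#'
#' @return Numeric vector `c(1, 0.5, 0.25, 0.2, 0.125, 0.1)`.
#' @export
admissible_factors <- function() c(1, 0.5, 0.25, 0.2, 0.125, 0.1)

#' Scaling-factor / kernel-size scan
#'
#' Trains one detector per (scaling factor, input-layer kernel size) cell
#' on the given records and reports the pooled F1 on the test records.
#' The kernel scanned is the first convolution of the leads-distillation
#' module (the input layer); set `scan_unet_kernel = TRUE` to scan the
#' U-Net level-0 kernel instead.
#'
#' @param train_records,test_records Lists of [ecg_record()]s.
#' @param factors Scaling factors, a subset of [admissible_factors()].
#' @param kernel_sizes Odd kernel sizes to scan.
#' @param epochs Training epochs per cell (desk scale: keep small).
#' @param seed Integer seed.
#' @param scan_unet_kernel Scan the U-Net level-0 kernel instead of the
#'   LDM input kernel?
#' @param quiet Suppress progress output?
#' @return A [tibble::tibble] with columns `scaling_factor`, `kernel_size`,
#'   `F1` (plus `Se`, `PPv`).
#' @export
scaling_scan <- function(train_records, test_records,
                         factors = c(1, 0.2), kernel_sizes = c(7, 11),
                         epochs = 5, seed = 0, scan_unet_kernel = FALSE,
                         quiet = TRUE) {
  stopifnot(length(train_records) > 0, length(test_records) > 0)
  if (!all(factors %in% admissible_factors()))
    stop("factors must be admissible scaling factors")
  rows <- list()
  for (f in factors) {
    tr <- unlist(lapply(train_records, prepare_training_windows, factor = f),
                 recursive = FALSE)
    te <- unlist(lapply(test_records, prepare_training_windows, factor = f),
                 recursive = FALSE)
    for (k in kernel_sizes) {
      ldm <- if (scan_unet_kernel) ldm_config() else
        ldm_config(kernel_width = k)
      unet <- if (scan_unet_kernel)
        unet_config(kernel_sizes = c(k, 17, 13)) else unet_config()
      cfg <- detector_config(ldm = ldm, unet = unet,
                             train = train_config(epochs = epochs,
                                                  seed = seed,
                                                  scaling_factor = f))
      model <- build_model(config = cfg, seed = seed)
      model <- train(model, tr, quiet = TRUE)
      met <- evaluate_windows(model, te, factor = f)
      if (!quiet)
        message(sprintf("factor %-5g kernel %2d  F1 %.2f", f, k, met$F1))
      rows[[length(rows) + 1L]] <-
        tibble::tibble(scaling_factor = f, kernel_size = k,
                       Se = met$Se, PPv = met$PPv, F1 = met$F1)
    }
  }
  do.call(rbind, rows)
}

#' Per-factor box statistics of a scan
#'
#' Summarizes the F1 scores of all kernel sizes for each scaling factor as
#' the median, quartiles, minimum and maximum.
#'
#' @param scan Result of [scaling_scan()].
#' @return A [tibble::tibble] with one row per scaling factor.
#' @export
scan_box_stats <- function(scan) {
  fs <- sort(unique(scan$scaling_factor), decreasing = TRUE)
  rows <- lapply(fs, function(f) {
    v <- scan$F1[scan$scaling_factor == f]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble::tibble(scaling_factor = f, min = min(v), q1 = q[1],
                   median = q[2], q3 = q[3], max = max(v))
  })
  do.call(rbind, rows)
}

#' Single-taper power spectrum
#'
#' Periodogram of the full window (magnitude-squared FFT, one taper, no
#' averaging), reported on the requested band.
#'
#' @param x Numeric signal (length >= 32).
#' @param fs Sampling frequency in Hz.
#' @param fmin,fmax Reported band edges in Hz (defaults 0.1 and 45).
#' @return A [tibble::tibble] with columns `frequency` (Hz) and `power`.
#' @export
power_spectrum <- function(x, fs, fmin = 0.1, fmax = 45) {
  n <- length(x)
  if (n < 32) stop("signal too short for a spectrum")
  p <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq >= fmin & freq <= min(fmax, fs / 2)
  tibble::tibble(frequency = freq[keep], power = p[keep])
}

#' Spectra of a signal before and after the scaling operation
#'
#' Computes the periodogram of (a) the original signal at `fs`, (b) the
#' stride-decimated signal at `fs * factor`, and (c) the decimated signal
#' upsampled back to length with nearest values at `fs`. Below the new
#' Nyquist `fs * factor / 2` the (b) and (c) curves agree up to the
#' zero-order-hold droop; content of (a) above the new Nyquist no longer
#' exists at its own frequency in (b) -- decimation without an anti-alias
#' filter folds it to a lower frequency rather than deleting its energy,
#' and the nearest-value images in (c) put an attenuated copy back above
#' the new Nyquist.
#'
#' @param x Numeric signal.
#' @param fs Sampling frequency in Hz.
#' @param factor Admissible scaling factor.
#' @param fmax Upper reported frequency (default 45 Hz).
#' @return List with `new_nyquist` (Hz), `spectra` (a tibble with columns
#'   `signal` in `original`/`downsampled`/`upsampled`, `frequency`,
#'   `power`), and `agreement` (mean relative power difference between (b)
#'   and (c) below the new Nyquist, power-weighted).
#' @export
compare_scaled_spectra <- function(x, fs, factor, fmax = 45) {
  check_scaling_factor(factor)
  new_nyq <- fs * factor / 2
  xd <- downsample(x, factor)
  xu <- upsample_prediction(xd, factor, length(x))
  sa <- power_spectrum(x, fs, fmin = 0.1, fmax = fmax)
  sb <- power_spectrum(xd, fs * factor, fmin = 0.1, fmax = fmax)
  sc <- power_spectrum(xu, fs, fmin = 0.1, fmax = fmax)
  spectra <- rbind(
    cbind(tibble::tibble(signal = "original"), sa),
    cbind(tibble::tibble(signal = "downsampled"), sb),
    cbind(tibble::tibble(signal = "upsampled"), sc))
  # (b) and (c) share the frequency resolution fs/length(x) when
  # length(x) is a multiple of 1/factor, so bins align below the new
  # Nyquist; compare power-weighted
  bb <- sb[sb$frequency < new_nyq, ]
  cc <- sc[sc$frequency < new_nyq, ]
  m <- min(nrow(bb), nrow(cc))
  agreement <- sum(abs(bb$power[seq_len(m)] / factor -
                         cc$power[seq_len(m)])) /
    sum(bb$power[seq_len(m)] / factor)
  list(new_nyquist = new_nyq, spectra = spectra, agreement = agreement)
}
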