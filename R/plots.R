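# ggplot2 views of records, distillation weights, detections and the
# experiment outputs.

#' Plot a multi-lead record with annotations
#'
#' @param record An [ecg_record()].
#' @param detected Optional detected R-peak indices to overlay.
#' @param t_range Optional c(start, end) in seconds to crop.
#' @return A ggplot object.
#' @export
plot_record <- function(record, detected = NULL, t_range = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  n <- ncol(record$signals)
  df <- data.frame(
    time = rep((seq_len(n) - 1) / record$fs, each = nrow(record$signals)),
    lead = factor(rep(record$lead_names, n), levels = record$lead_names),
    value = as.numeric(record$signals))
  if (!is.null(t_range))
    df <- df[df$time >= t_range[1] & df$time <= t_range[2], ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lead), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)")
  ref <- record$r_peaks / record$fs
  if (length(ref))
    p <- p + ggplot2::geom_vline(xintercept = ref, colour = "grey60",
                                 linetype = 3)
  if (!is.null(detected) && length(detected))
    p <- p + ggplot2::geom_vline(xintercept = detected / record$fs,
                                 colour = "red", linetype = 2, alpha = 0.6)
  p
}

#' Plot the distillation weight map of a window
#'
#' Heat map of the normalized per-sample lead weights (columns sum to 1):
#' leads the module trusts at each instant show up bright.
#'
#' @param weights H x W matrix from [ldm_forward()]`$weights`.
#' @param fs Sampling frequency of the (scaled) signal, for the time axis.
#' @return A ggplot object.
#' @export
plot_weight_map <- function(weights, fs = 1) {
  df <- data.frame(
    time = rep((seq_len(ncol(weights)) - 1) / fs, each = nrow(weights)),
    lead = rep(seq_len(nrow(weights)), ncol(weights)),
    weight = as.numeric(weights))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$lead,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(weights))) +
    ggplot2::labs(x = if (fs > 1) "time (s)" else "sample", y = "lead",
                  fill = "weight")
}

#' Box plot of a scaling-factor scan
#'
#' One box per scaling factor over the F1 scores of all scanned kernel
#' sizes.
#'
#' @param scan Result of [scaling_scan()].
#' @return A ggplot object.
#' @export
plot_scan <- function(scan) {
  scan$scaling_factor <- factor(scan$scaling_factor,
                                levels = sort(unique(scan$scaling_factor),
                                              decreasing = TRUE))
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$scaling_factor,
                                     y = .data$F1)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "scaling factor", y = "F1 score")
}

#' Plot the spectra around the scaling operation
#'
#' @param comparison Result of [compare_scaled_spectra()].
#' @return A ggplot object.
#' @export
plot_scaled_spectra <- function(comparison) {
  ggplot2::ggplot(comparison$spectra,
                  ggplot2::aes(x = .data$frequency, y = .data$power,
                               colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = comparison$new_nyquist,
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "frequency (Hz)", y = "power")
}
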