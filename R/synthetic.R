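# Synthetic multi-lead ECG with known R-peak ground truth and the
# corruptions that motivate multi-lead fusion: per-lead gain/polarity
# differences, baseline wander, broadband muscle noise, QRS-shaped fake
# beats on a minority of leads, and whole-lead dropout segments.

#' Synthetic record configuration
#'
#' @param n_leads Number of leads (default 12).
#' @param fs Sampling frequency in Hz, one of 250, 257, 360, 500
#'   (default 250).
#' @param duration Record duration in seconds (default 10).
#' @param mean_hr Mean heart rate in bpm (default 70).
#' @param rr_cv Coefficient of variation of the RR intervals (default 0.05).
#' @param lead_gains Per-lead amplitude multipliers, negative values flip
#'   polarity; default alternates and spreads gains over about 0.5-1.4.
#' @param baseline_amp Baseline-wander amplitude in mV (default 0.1).
#' @param baseline_freq Baseline-wander frequency in Hz (default 0.33).
#' @param noise_rms Broadband (muscle) noise RMS in mV (default 0.05).
#' @param fake_qrs_leads 0-based count of leads carrying fake-QRS
#'   artifacts, taken from the first leads (default 0; the end-to-end
#'   protocol uses up to 3 of 12).
#' @param fake_qrs_rate Fake-QRS events per minute on those leads
#'   (default 3).
#' @param dropout List of per-lead dropout spans, each element
#'   `list(lead =, start =, end =)` in samples (default none).
#' @param seed Integer seed (default 0).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_leads = 12, fs = 250, duration = 10,
                         mean_hr = 70, rr_cv = 0.05, lead_gains = NULL,
                         baseline_amp = 0.1, baseline_freq = 0.33,
                         noise_rms = 0.05, fake_qrs_leads = 0,
                         fake_qrs_rate = 3, dropout = list(), seed = 0) {
  if (!fs %in% c(250, 257, 360, 500)) stop("unsupported sampling frequency")
  stopifnot(n_leads >= 1, duration > 0, rr_cv >= 0,
            duration * mean_hr / 60 >= 1)
  if (is.null(lead_gains))
    lead_gains <- rep_len(c(1, 0.8, -0.7, 1.2, 0.6, -1, 0.9, 1.4,
                            0.5, 1.1, -0.8, 0.7), n_leads)
  stopifnot(length(lead_gains) == n_leads)
  structure(list(n_leads = as.integer(n_leads), fs = fs,
                 duration = duration, mean_hr = mean_hr, rr_cv = rr_cv,
                 lead_gains = lead_gains, baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq, noise_rms = noise_rms,
                 fake_qrs_leads = as.integer(fake_qrs_leads),
                 fake_qrs_rate = fake_qrs_rate, dropout = dropout,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# add one Gaussian bump in place, touching only samples within 5 sigma
add_bump <- function(sig, fs, center, width, amp) {
  n <- length(sig)
  lo <- max(1L, floor((center - 5 * width) * fs) + 1L)
  hi <- min(n, ceiling((center + 5 * width) * fs) + 1L)
  if (lo > hi) return(sig)
  tt <- (seq(lo, hi) - 1) / fs
  sig[lo:hi] <- sig[lo:hi] + amp * exp(-0.5 * ((tt - center) / width)^2)
  sig
}

# P-QRS-T as Gaussian bumps with fixed offsets/widths (seconds, mV); the
# QRS is a tall narrow R bump with small Q/S flanks so the rendered center
# is the R-peak by construction
add_beat <- function(sig, fs, beat_time) {
  sig <- add_bump(sig, fs, beat_time - 0.20, 0.030, 0.15)
  sig <- add_bump(sig, fs, beat_time - 0.030, 0.012, -0.10)
  sig <- add_bump(sig, fs, beat_time, 0.012, 1.00)
  sig <- add_bump(sig, fs, beat_time + 0.030, 0.012, -0.15)
  add_bump(sig, fs, beat_time + 0.25, 0.055, 0.30)
}

#' Generate a synthetic multi-lead ECG record
#'
#' Beat times come from Gaussian-perturbed RR intervals (mean `60/mean_hr`
#' seconds, sd `rr_cv` times the mean); each beat renders a P-QRS-T complex
#' as a sum of Gaussian bumps, scaled per lead by `lead_gains`. Baseline
#' wander, broadband noise, fake-QRS artifacts and dropout segments are
#' added after rendering, so the returned `r_peaks` (the rendered QRS
#' centers) are exact ground truth. Fully reproducible from the seed.
#'
#' @param config A [synth_config()].
#' @return An [ecg_record()] with ground-truth `r_peaks`.
#' @export
generate_record <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration * fs)
  t <- (seq_len(n) - 1) / fs
  rr_mean <- 60 / config$mean_hr
  n_max <- ceiling(config$duration / rr_mean * 2) + 10
  rr <- stats::rnorm(n_max, rr_mean, config$rr_cv * rr_mean)
  rr <- pmax(rr, 0.25)                   # refractory floor
  beat_times <- cumsum(c(0.5 * rr_mean, rr))
  beat_times <- beat_times[beat_times < config$duration - 0.5 / fs]
  r_peaks <- round(beat_times * fs)
  r_peaks <- r_peaks[r_peaks >= 0 & r_peaks < n]
  base <- numeric(n)
  for (bt in r_peaks / fs) base <- add_beat(base, fs, bt)
  signals <- matrix(0, config$n_leads, n)
  for (l in seq_len(config$n_leads)) {
    phase <- stats::runif(1, 0, 2 * pi)
    wander <- config$baseline_amp *
      sin(2 * pi * config$baseline_freq * t + phase)
    noise <- stats::rnorm(n, 0, config$noise_rms)
    signals[l, ] <- config$lead_gains[l] * base + wander + noise
  }
  rec <- ecg_record(signals, fs,
                    paste0("SL", seq_len(config$n_leads)),
                    sort(unique(r_peaks)))
  if (config$fake_qrs_leads > 0)
    rec <- add_fake_qrs(rec, seq_len(min(config$fake_qrs_leads,
                                         config$n_leads)),
                        config$fake_qrs_rate, seed = config$seed + 1L)
  for (dp in config$dropout)
    rec <- drop_lead_segments(rec, dp$lead, list(c(dp$start, dp$end)))
  rec
}

#' Insert fake QRS complexes on selected leads
#'
#' QRS-shaped transients (same narrow-bump morphology as real beats,
#' slightly attenuated) at uniform-random positions at least 300 ms away
#' from every true beat, on the specified leads only. The ground-truth
#' `r_peaks` are unchanged: these artifacts are exactly what the
#' leads-distillation module must learn to down-weight.
#'
#' @param record An [ecg_record()].
#' @param leads Integer indices (1-based) of leads to corrupt.
#' @param rate Expected events per minute per lead (>= 0).
#' @param seed Integer seed.
#' @return The corrupted record.
#' @export
add_fake_qrs <- function(record, leads, rate, seed = 0) {
  stopifnot(inherits(record, "ecg_record"))
  if (rate < 0) stop("rate must be >= 0")
  if (any(leads < 1 | leads > nrow(record$signals)))
    stop("lead index out of range")
  if (rate == 0) return(record)
  set.seed(seed)
  n <- ncol(record$signals)
  fs <- record$fs
  dur_min <- n / fs / 60
  guard <- 0.3                           # seconds from any true beat
  for (l in leads) {
    k <- stats::rpois(1, rate * dur_min)
    placed <- 0L
    tries <- 0L
    while (placed < k && tries < 200L) {
      tries <- tries + 1L
      pos <- stats::runif(1, 0.1, n / fs - 0.1)
      if (length(record$r_peaks) &&
          min(abs(pos - record$r_peaks / fs)) < guard) next
      sig <- record$signals[l, ]
      sig <- add_bump(sig, fs, pos, 0.012, 0.8)
      sig <- add_bump(sig, fs, pos - 0.03, 0.012, -0.1)
      record$signals[l, ] <- add_bump(sig, fs, pos + 0.03, 0.012, -0.12)
      placed <- placed + 1L
    }
  }
  record
}

#' Replace lead segments by low-amplitude noise (electrode dropout)
#'
#' @param record An [ecg_record()].
#' @param lead 1-based lead index.
#' @param spans List of `c(start, end)` 0-based half-open sample spans.
#' @param noise_rms RMS of the replacement noise in mV (default 0.01).
#' @param seed Integer seed.
#' @return The record with the segments replaced; `r_peaks` unchanged.
#' @export
drop_lead_segments <- function(record, lead, spans, noise_rms = 0.01,
                               seed = 0) {
  stopifnot(inherits(record, "ecg_record"))
  if (lead < 1 || lead > nrow(record$signals)) stop("lead index out of range")
  n <- ncol(record$signals)
  set.seed(seed)
  for (sp in spans) {
    if (sp[1] < 0 || sp[2] > n || sp[1] >= sp[2])
      stop("span outside record: [", sp[1], ", ", sp[2], ")")
    idx <- (sp[1] + 1L):sp[2]
    record$signals[lead, idx] <- stats::rnorm(length(idx), 0, noise_rms)
  }
  record
}
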