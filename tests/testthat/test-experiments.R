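test_that("the periodogram localizes tones and conserves energy", {
  fs <- 360
  n <- 4 * fs
  t <- (seq_len(n) - 1) / fs
  tone <- sin(2 * pi * 10 * t)
  sp <- power_spectrum(tone, fs)
  expect_equal(sp$frequency[which.max(sp$power)], 10, tolerance = 0.3)
  dc <- power_spectrum(rep(2, n), fs)
  expect_lt(max(dc$power), 1e-12)
  # Parseval: the one-sided band [0, Nyquist] accounts for the energy
  # once DC and Nyquist (unpaired bins) are counted singly
  x <- rnorm(512)
  side <- power_spectrum(x, fs = 1, fmin = 0, fmax = 1)
  total <- 2 * sum(side$power) - side$power[side$frequency == 0] -
    side$power[side$frequency == 0.5]
  expect_equal(total, sum(x^2), tolerance = 1e-8)
  expect_error(power_spectrum(rnorm(16), fs), "short")
})

test_that("the scaling operation's spectra behave as the mechanism states", {
  fs <- 360
  cmp_identity <- compare_scaled_spectra(rnorm(720), fs, 1)
  sp <- cmp_identity$spectra
  expect_equal(sp$power[sp$signal == "original"],
               sp$power[sp$signal == "upsampled"])
  expect_lt(cmp_identity$agreement, 1e-12)

  rec <- generate_record(synth_config(n_leads = 1, fs = fs, duration = 10,
                                      seed = 8))
  x <- bandpass_filter(rec$signals[1, ], fs)
  cmp <- compare_scaled_spectra(x, fs, 0.2)
  expect_equal(cmp$new_nyquist, 36)
  # below the new Nyquist the decimated and reconstructed spectra coincide
  # to within 10% power-weighted for band-passed ECG
  expect_lt(cmp$agreement, 0.10)
})

test_that("a 38 Hz probe aliases instead of vanishing; 10 Hz survives", {
  # frozen oracle values: stride decimation folds 38 Hz (fs 360, factor
  # 0.2, new Nyquist 36) onto 34 Hz, and the zero-order-hold image puts
  # power ratio ~0.375 back at 38 Hz; a 10 Hz tone keeps ~0.94
  fs <- 360
  scale_op <- function(x) upsample_prediction(downsample(x, 0.2), 0.2,
                                              length(x))
  g38 <- tone_gain(scale_op, 38, fs)^2
  g10 <- tone_gain(scale_op, 10, fs)^2
  expect_equal(g38, 0.375, tolerance = 0.02)
  expect_equal(g10, 0.940, tolerance = 0.02)
  # the folded copy appears at 34 Hz
  n <- 4 * fs
  t <- (seq_len(n) - 1) / fs
  y <- scale_op(sin(2 * pi * 38 * t))
  p <- Mod(stats::fft(y))^2
  expect_gt(p[round(34 * n / fs) + 1] / p[round(38 * n / fs) + 1], 1)
})

test_that("the scaling-factor scan produces one row per grid cell", {
  recs <- lapply(1:2, function(s)
    generate_record(synth_config(n_leads = 2, duration = 30,
                                 noise_rms = 0.02, seed = s)))
  te <- list(generate_record(synth_config(n_leads = 2, duration = 30,
                                          noise_rms = 0.02, seed = 10)))
  scan <- scaling_scan(recs, te, factors = c(1, 0.2),
                       kernel_sizes = c(7, 11), epochs = 2, seed = 0)
  expect_equal(nrow(scan), 4)
  expect_true(all(scan$scaling_factor %in% admissible_factors()))
  expect_true(all(is.finite(scan$F1)))
  box <- scan_box_stats(scan)
  expect_equal(nrow(box), 2)
  for (f in box$scaling_factor) {
    v <- scan$F1[scan$scaling_factor == f]
    expect_equal(box$median[box$scaling_factor == f],
                 unname(stats::quantile(v, 0.5)))
  }
  expect_error(scaling_scan(recs, te, factors = 0.3), "admissible")
})
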