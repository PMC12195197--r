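test_that("band-pass filter rejects DC, keeps the pass band, attenuates mains", {
  fs <- 360
  # DC is below the 1 Hz edge
  dc <- bandpass_filter(rep(1, 4 * fs), fs)
  trim <- (fs + 1):(3 * fs)
  expect_lt(max(abs(dc[trim])), 1e-6)
  # 10 Hz sits mid-band; 60 Hz mains is above the 40 Hz edge
  g10 <- tone_gain(function(x) bandpass_filter(x, fs), 10, fs)
  g60 <- tone_gain(function(x) bandpass_filter(x, fs), 60, fs)
  expect_gt(g10, 0.95)
  expect_lt(g10, 1.05)
  expect_lt(g60, 0.20)
  # zero phase: a clean peak must not move
  x <- numeric(2 * fs)
  x[fs] <- 1
  y <- bandpass_filter(x, fs)
  expect_equal(which.max(y), fs)
  expect_error(bandpass_filter(rnorm(100), 80), "Nyquist")
})

test_that("band-pass filtering twice changes pass-band gain by under 2%", {
  fs <- 250
  once <- tone_gain(function(x) bandpass_filter(x, fs), 10, fs)
  twice <- tone_gain(function(x) bandpass_filter(bandpass_filter(x, fs), fs),
                     10, fs)
  expect_lt(abs(twice - once), 0.02)
})

test_that("downsample implements stride decimation with admissible factors", {
  expect_length(downsample(rnorm(3600), 0.2), 720)
  expect_length(downsample(rnorm(2500), 0.2), 500)
  x <- rnorm(500)
  expect_identical(downsample(x, 1), x)
  expect_equal(downsample(seq_len(20), 0.25), c(1, 5, 9, 13, 17))
  m <- matrix(rnorm(2 * 100), 2)
  expect_equal(downsample(m, 0.5), m[, seq(1, 100, 2)])
  expect_error(downsample(x, 0.3), "integer")
  expect_error(downsample(x, 0))
  expect_error(downsample(x, 1.5))
})

test_that("nearest-value upsampling repeats each sample", {
  expect_equal(upsample_nearest(c(1, 2), 5), c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2))
  x <- rnorm(7)
  expect_identical(upsample_nearest(x, 1), x)
  expect_error(upsample_nearest(x, 0))
  # down then up conserves length for divisible N
  x <- rnorm(500)
  expect_length(upsample_nearest(downsample(x, 0.2), 5), 500)
  # and the dominant frequency of a band-limited tone survives
  fs <- 250
  n <- 1000
  tone <- sin(2 * pi * 7 * (seq_len(n) - 1) / fs)
  y <- upsample_nearest(downsample(tone, 0.2), 5)
  expect_equal(which.max(Mod(stats::fft(y))[2:(n / 2)]),
               which.max(Mod(stats::fft(tone))[2:(n / 2)]))
})

test_that("upsample_prediction crops to the original length", {
  p <- runif(500)
  expect_length(upsample_prediction(p, 0.2, 2500), 2500)
  for (n in c(2498, 2503)) {
    d <- downsample(rnorm(n), 0.2)
    expect_length(upsample_prediction(d, 0.2, n), n)
  }
  # a single detection at scaled index k expands to samples [5k, 5k+5)
  mask <- numeric(100)
  mask[11] <- 1                           # scaled index 10 (0-based)
  up <- upsample_prediction(mask, 0.2)
  expect_equal(which(up == 1) - 1, 50:54)
})

test_that("windowing covers the record and localizes beats", {
  fs <- 360
  rec <- ecg_record(matrix(rnorm(2 * 30 * fs), 2), fs,
                    r_peaks = c(100L, 3700L, 8000L))
  w <- segment_windows(rec)
  expect_length(w, 3)
  # beat at global index 3700 falls in the second window at local 100
  expect_equal(w[[2]]$offset, 3600)
  expect_equal(w[[2]]$r_peaks_local, 100L)
  # 35 s record: tail dropped by default
  rec35 <- ecg_record(matrix(rnorm(35 * fs), 1), fs)
  expect_length(segment_windows(rec35), 3)
  # with padding the tail window is kept, zero-padded and flagged
  wp <- segment_windows(rec35, pad_tail = TRUE)
  expect_length(wp, 4)
  expect_equal(wp[[4]]$n_valid, 5 * fs)
  expect_equal(ncol(wp[[4]]$signals), 10 * fs)
  # partition: window lengths plus dropped tail equal the record length
  w <- segment_windows(rec35)
  expect_equal(sum(vapply(w, function(x) x$n_valid, numeric(1))) + 5 * fs,
               35 * fs)
})

test_that("the axis transform is a bijection to H x W x 1 maps", {
  m <- matrix(rnorm(12 * 500), 12)
  a <- axis_transform(m)
  expect_equal(dim(a), c(12L, 500L, 1L))
  expect_equal(axis_untransform(a), m, ignore_attr = TRUE)
  expect_equal(dim(axis_transform(rnorm(720))), c(1L, 720L, 1L))
  expect_error(axis_transform(matrix(numeric(0), 0, 0)), "empty")
})
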