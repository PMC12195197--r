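test_that("label width follows the 150 ms rule at every standard rate", {
  expect_identical(label_width(257), 39L)
  expect_identical(label_width(360), 55L)
  expect_identical(label_width(500), 75L)
  for (fs in c(250, 257, 360, 500)) {
    w <- label_width(fs)
    expect_true(w %% 2 == 1)
    # "about 150 ms": the printed width 55 @ 360 Hz itself is 152.8 ms
    expect_gte(w / fs, 0.144)
    expect_lte(w / fs, 0.153)
  }
})

test_that("masks mark symmetric label regions and truncate at edges", {
  m <- make_mask(100, 300, 257)
  expect_equal(sum(m), 39)
  on <- which(m == 1) - 1
  expect_equal(range(on), c(100 - 19, 100 + 19))
  expect_equal(make_mask(integer(0), 50, 257), integer(50))
  # peak near the boundary: [0, 24], 25 ones
  m5 <- make_mask(5, 300, 257)
  expect_equal(sum(m5), 25)
  expect_equal(range(which(m5 == 1) - 1), c(0, 24))
  expect_error(make_mask(400, 300, 257), "length")
})

test_that("mask construction is monotone and bounded", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 500
    fs <- sample(c(250, 257, 360, 500), 1)
    peaks <- sort(sample(0:(n - 1), 5))
    m1 <- make_mask(peaks[-1], n, fs)
    m2 <- make_mask(peaks, n, fs)
    expect_true(all(m2 >= m1))           # adding a peak never clears a 1
    expect_lte(sum(m2), length(peaks) * label_width(fs))
  }
})

test_that("mask decimation keeps the signal's stride and phase", {
  # a 39-wide label keeps 7 or 8 ones at factor 0.2, depending on phase
  for (phase in 0:4) {
    m <- make_mask(60 + phase, 300, 257)
    d <- decimate_mask(m, 0.2)
    span <- which(m == 1) - 1
    expected <- sum(span %% 5 == 0)      # surviving stride-5 samples
    expect_equal(sum(d), expected)
    expect_true(sum(d) %in% c(7L, 8L))
  }
  expect_equal(decimate_mask(integer(100), 0.2), integer(20))
  m <- make_mask(10, 50, 257)
  expect_identical(decimate_mask(m, 1), m)
})
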