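test_that("binarization thresholds with ties counting as detections", {
  expect_equal(binarize(c(0.4, 0.6)), c(0L, 1L))
  expect_equal(binarize(rep(0.5, 4)), rep(1L, 4))
  set.seed(31)
  p <- runif(200)
  expect_equal(binarize(p, 0.3), as.integer(p >= 0.3))
  expect_error(binarize(p, 1.2), "threshold")
})

test_that("regions become peaks at run midpoints, short runs are dropped", {
  fs <- 257
  mask <- integer(300)
  mask[(100:138) + 1] <- 1L
  expect_equal(mask_to_peaks(mask, fs), 119L)
  short <- integer(300)
  short[(50:52) + 1] <- 1L                # ~11.7 ms, under the 40 ms floor
  expect_length(mask_to_peaks(short, fs), 0)
  expect_length(mask_to_peaks(integer(100), fs), 0)
  # random masks agree with a scan-based run-extraction oracle
  set.seed(32)
  for (rep in 1:10) {
    m <- as.integer(runif(400) > 0.7)
    runs <- oracle_runs(m)
    keep <- Filter(function(r) (r[2] - r[1] + 1) >= fs * 0.04, runs)
    want <- vapply(keep, function(r) (r[1] + r[2]) %/% 2, numeric(1))
    expect_equal(mask_to_peaks(m, fs), as.integer(sort(want)))
  }
})

test_that("beat matching applies the 75 ms centered region, one-to-one", {
  ref <- c(100L, 500L, 900L)
  m <- match_beats(ref, ref, 360)
  expect_equal(c(m$TP, m$FP, m$FN), c(3L, 0L, 0L))
  # 50 ms offset at 360 Hz is 18 samples, beyond the 13-sample tolerance
  m2 <- match_beats(118L, 100L, 360)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(0L, 1L, 1L))
  # 37.5 ms at 360 Hz is 13.5 samples: 13 is inside the region, 14 is out
  expect_equal(match_beats(113L, 100L, 360)$TP, 1L)
  expect_equal(match_beats(114L, 100L, 360)$TP, 0L)
  expect_error(match_beats(c(5L, 2L), ref, 360), "sorted")
  # counts always partition both lists
  expect_equal(m2$TP + m2$FN, 1L)
  expect_equal(m2$TP + m2$FP, 1L)
})

test_that("greedy matching tracks the optimal assignment on random beats", {
  set.seed(33)
  fs <- 257
  tol <- round(0.0375 * fs)
  mismatches <- 0
  for (rep in 1:30) {
    ref <- sort(sample(0:5000, 50))
    det <- ref + sample(-6:6, 50, replace = TRUE)
    det <- sort(unique(c(det[runif(50) > 0.1],
                         sample(0:5000, 5))))      # drops + spurious
    g <- match_beats(det, ref, fs)
    opt <- oracle_max_matching(det, ref, tol)
    expect_lte(g$TP, opt)
    expect_gte(g$TP, opt - 1L)           # never loses more than one pair
    if (g$TP != opt) mismatches <- mismatches + 1
    # a global time shift changes nothing
    s <- match_beats(det + 1000L, ref + 1000L, fs)
    expect_equal(s$TP, g$TP)
  }
  # greedy nearest-in-time rarely loses to the exhaustive assignment
  expect_lte(mismatches, 6)
})

test_that("extra detections cannot raise Se; removals cannot raise PPv", {
  set.seed(34)
  fs <- 250
  ref <- sort(sample(0:3000, 25))
  det <- sort(unique(ref + sample(-5:5, 25, replace = TRUE)))
  base <- compute_metrics(match_beats(det, ref, fs))
  more <- sort(unique(c(det, sample(0:3000, 10))))
  fewer <- det[-sample(length(det), 5)]
  expect_lte(compute_metrics(match_beats(more, ref, fs))$Se - 1e-9, base$Se)
  expect_lte(compute_metrics(match_beats(fewer, ref, fs))$PPv - 1e-9,
             base$PPv)
})

test_that("metrics follow the printed formulas and the harmonic identity", {
  m <- compute_metrics(list(TP = 9, FP = 1, FN = 1))
  expect_equal(c(m$Se, m$PPv, m$F1), c(90, 90, 90))
  perfect <- compute_metrics(list(TP = 7, FP = 0, FN = 0))
  expect_equal(c(perfect$Se, perfect$PPv, perfect$F1), c(100, 100, 100))
  big <- compute_metrics(list(TP = 997, FP = 3, FN = 5))
  expect_equal(big$Se, 997 / 1002 * 100)
  expect_equal(big$PPv, 99.7)
  expect_equal(big$F1, 2 * 997 / (2 * 997 + 8) * 100)
  set.seed(35)
  for (rep in 1:20) {
    tp <- sample(1:500, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    mm <- compute_metrics(list(TP = tp, FP = fp, FN = fn))
    expect_equal(mm$F1, 2 * mm$Se * mm$PPv / (mm$Se + mm$PPv))
  }
  undef <- compute_metrics(list(TP = 0, FP = 0, FN = 0))
  expect_true(is.na(undef$Se) && is.na(undef$PPv) && is.na(undef$F1))
  expect_false(undef$defined)
})
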