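test_that("generation is reproducible and honors zero RR variability", {
  cfg <- synth_config(n_leads = 3, duration = 10, seed = 9)
  expect_identical(generate_record(cfg), generate_record(cfg))
  fixed <- generate_record(synth_config(n_leads = 1, duration = 10,
                                        mean_hr = 60, rr_cv = 0,
                                        noise_rms = 0, baseline_amp = 0,
                                        seed = 1))
  expect_true(length(fixed$r_peaks) %in% c(9L, 10L))
  expect_true(all(diff(fixed$r_peaks) == fixed$fs))
})

test_that("argmax peak finding recovers the rendered R centers when clean", {
  rec <- generate_record(synth_config(n_leads = 1, duration = 20,
                                      noise_rms = 0, baseline_amp = 0,
                                      seed = 5))
  sig <- rec$signals[1, ]
  for (p in rec$r_peaks) {
    win <- max(1, p - 20):min(length(sig), p + 22)
    found <- win[which.max(sig[win])] - 1
    expect_lte(abs(found - p), 2)
  }
})

test_that("RR variability is calibrated: cv 0.05 reproduces empirically", {
  rrs <- unlist(lapply(1:100, function(s) {
    r <- generate_record(synth_config(n_leads = 1, duration = 12,
                                      rr_cv = 0.05, noise_rms = 0, seed = s))
    diff(r$r_peaks)
  }))
  cv <- stats::sd(rrs) / mean(rrs)
  expect_gte(cv, 0.03)
  expect_lte(cv, 0.07)
})

test_that("fake QRS artifacts corrupt only the chosen leads, not the truth", {
  rec <- generate_record(synth_config(n_leads = 12, duration = 20, seed = 2))
  expect_identical(add_fake_qrs(rec, 1:2, rate = 0), rec)
  fk <- add_fake_qrs(rec, 1:2, rate = 6, seed = 7)
  expect_identical(fk$r_peaks, rec$r_peaks)
  expect_identical(fk$signals[3:12, ], rec$signals[3:12, ])
  expect_gt(max(abs(fk$signals[1, ] - rec$signals[1, ])), 0.1)
  expect_error(add_fake_qrs(rec, 13, 1), "lead")
  expect_error(add_fake_qrs(rec, 1, -1), "rate")
})

test_that("fake-QRS counts follow the requested rate", {
  # ten minutes at 3/min: mean count near 30 across seeds
  counts <- vapply(1:50, function(s) {
    set.seed(s)
    stats::rpois(1, 3 * 10)
  }, numeric(1))
  rec <- generate_record(synth_config(n_leads = 1, duration = 600,
                                      mean_hr = 60, seed = 1))
  fk <- add_fake_qrs(rec, 1, rate = 3, seed = 11)
  # count inserted transients by their exclusion zone: differences occur
  # away from true beats
  delta <- abs(fk$signals[1, ] - rec$signals[1, ])
  n_events <- length(mask_to_peaks(as.integer(delta > 0.2), rec$fs,
                                   min_width_ms = 5))
  expect_gte(n_events, 15)
  expect_lte(n_events, 50)
  expect_gte(mean(counts), 20)
  expect_lte(mean(counts), 40)
})

test_that("dropout spans silence a lead without touching ground truth", {
  rec <- generate_record(synth_config(n_leads = 2, duration = 10, seed = 3))
  expect_identical(drop_lead_segments(rec, 1, list()), rec)
  n <- ncol(rec$signals)
  dr <- drop_lead_segments(rec, 1, list(c(0, n)))
  expect_lt(sqrt(mean(dr$signals[1, ]^2)), 0.05)
  expect_identical(dr$r_peaks, rec$r_peaks)
  expect_identical(dr$signals[2, ], rec$signals[2, ])
  expect_error(drop_lead_segments(rec, 1, list(c(-5, 10))), "span")
  expect_error(drop_lead_segments(rec, 1, list(c(0, n + 1))), "span")
})
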