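test_that("WFDB records round-trip through header, signal and annotations", {
  dir <- withr::local_tempdir()
  rec <- generate_record(synth_config(n_leads = 2, duration = 10, seed = 3))
  write_wfdb_record(rec, dir, "rt")
  back <- read_wfdb_record(file.path(dir, "rt"))
  expect_equal(back$fs, rec$fs)
  expect_equal(back$lead_names, rec$lead_names)
  expect_equal(back$r_peaks, rec$r_peaks)
  # 16-bit quantization at gain 200 is half a count, 0.0025 mV
  expect_lt(max(abs(back$signals - rec$signals)), 0.003)
})

test_that("lead subsets select and reorder; absent leads are named", {
  dir <- withr::local_tempdir()
  sig <- matrix(rnorm(12 * 100), 12)
  rec <- ecg_record(sig, 257, c("I", "II", "III", "avR", "avL", "avF",
                                paste0("V", 1:6)), r_peaks = 50L)
  write_wfdb_record(rec, dir, "twelve")
  one <- read_wfdb_record(file.path(dir, "twelve"), lead_subset = "II")
  expect_equal(nrow(one$signals), 1)
  expect_equal(one$lead_names, "II")
  two <- read_wfdb_record(file.path(dir, "twelve"),
                          lead_subset = c("V2", "I"))
  expect_equal(two$lead_names, c("V2", "I"))
  expect_error(read_wfdb_record(file.path(dir, "twelve"),
                                lead_subset = "X9"), "X9")
})

test_that("only beat-class annotation symbols become r_peaks", {
  dir <- withr::local_tempdir()
  rec <- ecg_record(matrix(rnorm(300), 1), 257)
  write_wfdb_record(rec, dir, "sym")
  write_wfdb_annotation(file.path(dir, "sym"),
                        c(20L, 50L, 90L, 150L, 200L),
                        c("N", "+", "V", "~", "L"))
  back <- read_wfdb_record(file.path(dir, "sym"))
  expect_equal(back$r_peaks, c(20L, 90L, 200L))
})

test_that("annotation files handle long gaps and missing files", {
  dir <- withr::local_tempdir()
  base <- file.path(dir, "gap")
  samples <- c(10L, 5000L, 200000L)      # gaps far beyond 1023 samples
  write_wfdb_annotation(base, samples, rep("N", 3))
  ann <- read_wfdb_annotation(base)
  expect_equal(ann$sample, samples)
  rec <- ecg_record(matrix(rnorm(300), 1), 257)   # no annotated beats
  write_wfdb_record(rec, dir, "noann")
  expect_error(read_wfdb_record(file.path(dir, "noann")), "annotation")
  ok <- read_wfdb_record(file.path(dir, "noann"),
                         require_annotation = FALSE)
  expect_length(ok$r_peaks, 0)
})
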