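test_that("output length equals input length for awkward lengths", {
  m <- build_model(seed = 0)
  for (L in c(500, 514, 720, 101)) {
    p <- detect_probabilities(m, rnorm(L))
    expect_length(p, L)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("inference is deterministic and rejects bad input", {
  m <- build_model(seed = 0)
  s <- rnorm(300)
  expect_identical(detect_probabilities(m, s), detect_probabilities(m, s))
  expect_error(detect_probabilities(m, numeric(0)), "empty")
  expect_error(detect_probabilities(m, c(1, NA, 3)), "finite")
})

test_that("parameter count is input- and lead-independent, and enumerable", {
  m <- build_model(seed = 0)
  n0 <- count_parameters(m)
  invisible(detect_probabilities(m, rnorm(500)))
  invisible(ldm_forward(m, axis_transform(matrix(rnorm(12 * 100), 12))))
  expect_identical(count_parameters(m), n0)
  # independent enumeration from the architecture description
  ldm_count <- (13 * 11 * 1 + 13 + 2 * 13) +             # conv unit + BN
    (13 * 11 + 13 + 2 * 13) +                            # depth-wise + BN
    (13 * 1 * 13 + 13 + 2 * 13) +                        # point-wise + BN
    (11 * 13 * 1 + 1)                                    # squeeze conv
  unit <- function(k, cin, f = 3) f * k * cin + f + 2 * f
  unet_count <-
    unit(11, 1) + 2 * unit(11, 3) +                      # encoder level 0
    3 * unit(17, 3) +                                    # encoder level 1
    3 * unit(13, 3) +                                    # bottom level
    unit(17, 6) + 2 * unit(17, 3) +                      # decoder level 1
    unit(11, 6) + 2 * unit(11, 3) +                      # decoder level 0
    (3 + 1)                                              # 1x1 head
  expect_identical(n0, as.integer(ldm_count + unet_count))
})

test_that("pooling halves (ceiling) and the paired upsampling restores", {
  for (L in c(10, 11, 514)) {
    x <- array(rnorm(2 * L * 3), c(2, L, 3))
    p <- qrsdistill:::pool2_fwd(x)
    expect_equal(dim(p$out)[2], ceiling(L / 2))
    u <- qrsdistill:::up2_fwd(p$out, L)
    expect_equal(dim(u$out)[2], L)
  }
})
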