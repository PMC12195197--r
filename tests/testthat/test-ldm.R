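test_that("leaky ReLU keeps positives and scales negatives by 0.3", {
  expect_equal(leaky_relu(-1), -0.3)
  expect_equal(leaky_relu(2), 2)
  expect_equal(leaky_relu(0), 0)
  x <- array(rnorm(24), c(2, 4, 3))
  expect_equal(leaky_relu(x, 0.3), oracle_lrelu(x, 0.3), ignore_attr = TRUE)
})

test_that("the convolution unit matches a direct oracle", {
  # identity kernel (center tap 1) with identity BN reproduces the input
  w <- array(0, c(3, 1, 2))
  w[2, 1, ] <- 1
  x <- array(abs(rnorm(40)) + 0.1, c(2, 20, 1))
  out <- conv_unit(x, w, bias = c(0, 0))
  expect_equal(out[, , 1], x[, , 1], tolerance = 1e-4, ignore_attr = TRUE)
  # zero input stays zero
  expect_equal(conv_unit(array(0, c(1, 10, 1)), w, c(0, 0)),
               array(0, c(1, 10, 2)), tolerance = 1e-12)
  # 1x5x1 input against the hand-convolved sequence
  set.seed(1)
  x5 <- array(rnorm(5), c(1, 5, 1))
  k <- array(c(1, 0, -1), c(3, 1, 1))
  got <- conv_unit(x5, k, bias = 0)
  want <- oracle_lrelu(oracle_conv(x5, k, 0))
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("the depth-wise separable unit preserves under identity kernels", {
  n <- 3
  dw <- matrix(0, 3, n); dw[2, ] <- 1
  pw <- array(0, c(1, n, n))
  for (i in seq_len(n)) pw[1, i, i] <- 1
  x <- array(abs(rnorm(60)) + 0.1, c(2, 10, n))
  out <- ds_conv_unit(x, dw, rep(0, n), pw, rep(0, n))
  expect_equal(out, x, tolerance = 1e-4)
  expect_error(ds_conv_unit(array(0, c(1, 5, 2)), dw, rep(0, n), pw,
                            rep(0, n)), "channel")
})

test_that("the LDM holds the printed parameter counts per group", {
  m <- build_model(seed = 0)
  count_of <- function(prefix)
    count_parameters(m$params[startsWith(names(m$params), prefix)])
  # a lone 13-filter 1x11 conv: 13*11 weights + 13 biases
  expect_equal(length(m$params$ldm.cu.w) + length(m$params$ldm.cu.b), 156)
  # DS unit: depth-wise 13x11+13, point-wise 13x13+13, two BN pairs
  expect_equal(count_of("ldm.dw") + count_of("ldm.pw"),
               (13 * 11 + 13 + 26) + (13 * 13 + 13 + 26))
  expect_equal(count_parameters(list()), 0)
})

test_that("the raw weight map lies strictly inside (0, 1)", {
  w <- array(0, c(3, 4, 1))
  x <- array(rnorm(2 * 10 * 4), c(2, 10, 4))
  expect_true(all(weight_map(x, w, 0) == 0.5))
  expect_true(all(weight_map(x, w, 30) < 1))
  expect_true(all(weight_map(x, w, 30) > 0.999))
  set.seed(2)
  w <- array(rnorm(12, sd = 0.3), c(3, 4, 1))
  b <- 0.1
  got <- weight_map(x, w, b)
  want <- 1 / (1 + exp(-oracle_conv(x, w, b)[, , 1]))
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("column softmax is column-stochastic with closed-form values", {
  expect_equal(column_softmax(rnorm(6)), matrix(1, 1, 6))
  expect_equal(column_softmax(matrix(5, 4, 3)), matrix(0.25, 4, 3))
  expect_equal(column_softmax(matrix(c(0, log(3)), 2, 1)),
               matrix(c(0.25, 0.75), 2, 1))
  set.seed(3)
  for (H in c(2, 5, 12)) {
    A <- matrix(rnorm(H * 7, sd = 3), H)
    expect_equal(colSums(column_softmax(A)), rep(1, 7), tolerance = 1e-6)
  }
})

test_that("distillation is the weighted column sum", {
  x <- rnorm(8)
  expect_equal(distill_signal(x, rep(1, 8)), x, ignore_attr = TRUE)
  expect_equal(distill_signal(matrix(c(2, 4), 2, 1),
                              matrix(0.5, 2, 1)), 3)
  set.seed(4)
  X <- matrix(rnorm(12), 3, 4)
  A <- column_softmax(matrix(rnorm(12), 3, 4))
  want <- vapply(1:4, function(j) sum(X[, j] * A[, j]), numeric(1))
  expect_equal(distill_signal(X, A), want)
})

test_that("the full LDM is lead-count agnostic and matches the loop oracle", {
  m <- build_model(seed = 1)
  # one set of weights serves 12 and 2 leads without reconfiguration
  for (H in c(12, 2)) {
    out <- ldm_forward(m, axis_transform(matrix(rnorm(H * 50), H)))
    expect_length(out$distilled, 50)
    expect_equal(colSums(out$weights), rep(1, 50), tolerance = 1e-6)
  }
  # with one lead the softmax forces A' = 1 and the lead passes through
  x1 <- matrix(rnorm(64), 1)
  out1 <- ldm_forward(m, axis_transform(x1))
  expect_equal(out1$distilled, as.numeric(x1))
  # straight-loop oracle equivalence on a small map with nontrivial
  # running statistics
  cfg <- detector_config(ldm = ldm_config(n_filters = 4, kernel_width = 3,
                                          squeeze_kernel = 3))
  mt <- build_model(config = cfg, seed = 2)
  set.seed(5)
  for (nm in names(mt$stats)) {
    if (grepl("^ldm.*rm$", nm)) mt$stats[[nm]] <- rnorm(length(mt$stats[[nm]]), sd = 0.2)
    if (grepl("^ldm.*rv$", nm)) mt$stats[[nm]] <- runif(length(mt$stats[[nm]]), 0.5, 2)
  }
  x <- axis_transform(matrix(rnorm(24), 3, 8))
  got <- ldm_forward(mt, x)
  want <- oracle_ldm(mt, x)
  expect_equal(got$distilled, want$distilled, tolerance = 1e-6)
  expect_equal(got$weights, want$weights, tolerance = 1e-6)
})

test_that("distilled samples stay inside the per-column lead envelope", {
  m <- build_model(seed = 3)
  set.seed(6)
  for (rep in 1:5) {
    H <- sample(2:12, 1)
    x <- matrix(rnorm(H * 40), H)
    out <- ldm_forward(m, axis_transform(x))
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    expect_true(all(out$distilled >= lo - 1e-8))
    expect_true(all(out$distilled <= hi + 1e-8))
  }
})

test_that("permuting leads permutes the weights and keeps the signal", {
  m <- build_model(seed = 4)
  set.seed(7)
  x <- matrix(rnorm(6 * 30), 6)
  perm <- sample(6)
  a <- ldm_forward(m, axis_transform(x))
  b <- ldm_forward(m, axis_transform(x[perm, ]))
  expect_equal(b$distilled, a$distilled, tolerance = 1e-10)
  expect_equal(b$weights, a$weights[perm, ], tolerance = 1e-10)
})
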