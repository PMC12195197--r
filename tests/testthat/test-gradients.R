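# The training path is hand-written; finite differences on a small
# double-precision instance are the authority for every parameter group.

grad_check <- function(cfg, H, B, W, seed = 1, eps = 1e-5) {
  m <- build_model(config = cfg, seed = seed)
  set.seed(seed)
  x <- array(rnorm(B * H * W), c(B * H, W, 1))
  t <- matrix(rbinom(B * W, 1, 0.3), B, W)
  loss_fn <- function(params) {
    mm <- m
    mm$params <- params
    fwd <- qrsdistill:::model_forward_train(mm, x, H, B, training = TRUE,
                                            single = FALSE)
    qrsdistill:::dice_loss_batch(fwd$prob, t)$loss
  }
  fwd <- qrsdistill:::model_forward_train(m, x, H, B, training = TRUE,
                                          single = FALSE)
  dl <- qrsdistill:::dice_loss_batch(fwd$prob, t)
  grads <- qrsdistill:::model_backward_train(fwd, dl$dp)
  worst <- 0
  for (nm in names(m$params)) {
    g <- as.numeric(grads[[nm]])
    expect_false(is.null(grads[[nm]]), label = paste("gradient for", nm))
    p <- m$params[[nm]]
    idx <- if (length(p) > 8) sort(sample(length(p), 8)) else seq_along(p)
    for (i in idx) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      worst <- max(worst, abs(num - g[i]))
    }
  }
  worst
}

test_that("analytic gradients match finite differences (shallow net)", {
  set.seed(11)
  cfg <- detector_config(
    ldm = ldm_config(n_filters = 3, kernel_width = 3, squeeze_kernel = 3),
    unet = unet_config(filter_size = 2, depth = 1, levels = 1,
                       kernel_sizes = c(3, 3)))
  expect_lt(grad_check(cfg, H = 3, B = 2, W = 13), 1e-7)
})

test_that("analytic gradients survive two pooling levels and odd lengths", {
  set.seed(12)
  cfg <- detector_config(
    ldm = ldm_config(n_filters = 2, kernel_width = 3, squeeze_kernel = 3),
    unet = unet_config(filter_size = 2, depth = 2, levels = 2,
                       kernel_sizes = c(3, 5, 3)))
  expect_lt(grad_check(cfg, H = 2, B = 2, W = 23), 1e-7)
})

test_that("single-precision gradients track the double-precision ones", {
  set.seed(13)
  cfg <- detector_config(
    ldm = ldm_config(n_filters = 3, kernel_width = 3, squeeze_kernel = 3),
    unet = unet_config(filter_size = 2, depth = 1, levels = 1,
                       kernel_sizes = c(3, 3)))
  m <- build_model(config = cfg, seed = 2)
  H <- 3; B <- 2; W <- 17
  x <- array(rnorm(B * H * W), c(B * H, W, 1))
  t <- matrix(rbinom(B * W, 1, 0.3), B, W)
  g <- lapply(c(FALSE, TRUE), function(single) {
    fwd <- qrsdistill:::model_forward_train(m, x, H, B, training = TRUE,
                                            single = single)
    dl <- qrsdistill:::dice_loss_batch(fwd$prob, t)
    qrsdistill:::model_backward_train(fwd, dl$dp)
  })
  rel <- mapply(function(a, b) max(abs(a - b)) / (max(abs(a)) + 1e-6),
                g[[1]][names(g[[2]])], g[[2]])
  expect_lt(max(rel), 0.05)
})
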