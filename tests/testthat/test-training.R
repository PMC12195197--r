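test_that("the dice coefficient follows its closed form", {
  expect_equal(dice_coefficient(rep(1, 100), rep(1, 100)),
               200 / (200 + 1e-5))
  expect_equal(dice_coefficient(c(1, 0), c(0, 1)), 0)
  expect_equal(dice_coefficient(c(0.5, 0.5), c(1, 0)),
               1 / (1.5 + 1e-5))
  expect_equal(dice_loss(c(1, 0), c(0, 1)), 1)
  expect_equal(dice_loss(rep(1, 100), rep(1, 100)), 1 - 200 / (200 + 1e-5))
  # two empty masks give coefficient 0, loss 1 (the 0/delta convention)
  expect_equal(dice_loss(numeric(10), numeric(10)), 1)
  expect_error(dice_coefficient(1:3, 1:4), "length")
})

test_that("dice is symmetric, bounded and improves toward the target", {
  set.seed(21)
  for (rep in 1:20) {
    p <- runif(50)
    t <- rbinom(50, 1, 0.4)
    d <- dice_coefficient(p, t)
    expect_equal(d, dice_coefficient(t, p))
    expect_gte(d, 0)
    expect_lt(d, 1)
    expect_equal(d, oracle_dice(p, t))
  }
  # moving the prediction elementwise toward the target lowers the loss
  t <- rbinom(80, 1, 0.3)
  p <- runif(80)
  losses <- vapply(seq(0, 1, 0.25),
                   function(a) dice_loss(p + a * (t - p), t), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("training is reproducible and a no-op at zero epochs", {
  wins <- make_tiny_windows(12, seed = 100)
  cfg <- train_config(epochs = 3, seed = 0, batch_size = 8)
  m <- build_model(seed = 0)
  m1 <- train(m, wins, cfg)
  m2 <- train(m, wins, cfg)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(m1$params, m2$params)
  m0 <- train(m, wins, train_config(epochs = 0, seed = 0))
  expect_identical(m0$params, m$params)
  expect_equal(nrow(m0$history), 0)
  expect_error(train(m, list()), "empty")
})

test_that("clean synthetic data trains below 0.2 dice loss in 30 epochs", {
  wins <- make_tiny_windows(21, seed = 200, n_leads = 1, noise_rms = 0.005)
  m <- build_model(seed = 0)
  m <- train(m, wins, train_config(epochs = 30, seed = 0, batch_size = 2,
                                   val_fraction = 0))
  expect_lt(tail(m$history$train_loss, 1), 0.2)
  # losses trend downward overall
  h <- m$history$train_loss
  expect_lt(mean(tail(h, 5)), mean(head(h, 5)))
})

test_that("windows without any QRS target are excluded from training", {
  wins <- make_tiny_windows(6, seed = 300)
  empty <- wins[[1]]
  empty$mask <- integer(length(empty$mask))
  m <- build_model(seed = 0)
  expect_no_error(train(m, c(wins, list(empty)),
                        train_config(epochs = 1, seed = 0, batch_size = 4)))
})
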