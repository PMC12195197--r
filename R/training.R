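# Dice loss, Adam and the windowed training loop.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs Training epochs (default 100).
#' @param dice_smooth Smoothing constant in the dice denominator
#'   (default 1e-5).
#' @param seed Integer seed controlling initialization, shuffling and the
#'   validation split (default 0).
#' @param batch_size Windows per batch (default 16).
#' @param scaling_factor Scaling factor of the paired down/up-sampling
#'   (default 0.2; admissible values have an integer reciprocal).
#' @param val_fraction Fraction of training windows held out to select the
#'   best checkpoint (default 0.1).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 100,
                         dice_smooth = 1e-5, seed = 0, batch_size = 16,
                         scaling_factor = 0.2, val_fraction = 0.1) {
  stopifnot(dice_smooth > 0, learning_rate > 0, epochs >= 0,
            batch_size >= 1, val_fraction >= 0, val_fraction < 1)
  check_scaling_factor(scaling_factor)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 dice_smooth = dice_smooth, seed = as.integer(seed),
                 batch_size = as.integer(batch_size),
                 scaling_factor = scaling_factor,
                 val_fraction = val_fraction),
            class = "train_config")
}

#' Dice coefficient of a prediction against a binary target
#'
#' `2 * sum(p * t) / (sum(p^2) + sum(t^2) + smooth)`. The smoothing
#' constant in the denominator keeps the value strictly below 1 and the
#' gradient finite; two empty masks yield 0 under this formula (and hence
#' loss 1), which is why all-zero-target windows are excluded from training
#' batches.
#'
#' @param p Numeric prediction in `[0, 1]`.
#' @param t Binary target of the same length.
#' @param smooth Denominator smoothing (default 1e-5).
#' @return Scalar in `[0, 1)`.
#' @export
dice_coefficient <- function(p, t, smooth = 1e-5) {
  if (length(p) != length(t)) stop("prediction and target lengths differ")
  2 * sum(p * t) / (sum(p^2) + sum(t^2) + smooth)
}

#' Dice loss: one minus the dice coefficient
#'
#' @inheritParams dice_coefficient
#' @return Scalar in `(0, 1]`.
#' @export
dice_loss <- function(p, t, smooth = 1e-5) {
  1 - dice_coefficient(p, t, smooth)
}

dice_loss_batch <- function(p, t, smooth = 1e-5) {
  # p, t: B x W matrices; mean per-window dice loss and its gradient in p
  num <- 2 * rowSums(p * t)
  den <- rowSums(p^2) + rowSums(t^2) + smooth
  loss <- mean(1 - num / den)
  B <- nrow(p)
  dp <- -(2 * t * den - num * 2 * p) / den^2 / B
  list(loss = loss, dp = dp)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

model_forward_train <- function(model, x, H, B, training = TRUE,
                                single = TRUE) {
  lf <- ldm_forward_batch(x, model$params, model$stats, H = H, B = B,
                          training = training,
                          slope = model$cfg$ldm$lrelu_slope,
                          single = single)
  uf <- unet_forward_batch(lf$out, model$params, lf$stats, model$cfg$unet,
                           training = training,
                           slope = model$cfg$ldm$lrelu_slope)
  list(prob = uf$out, p = uf$p, stats = uf$stats,
       ldm_cache = lf$cache, unet_cache = uf$cache)
}

model_backward_train <- function(fwd, dprob) {
  ub <- unet_backward_batch(dprob, fwd$unet_cache, fwd$p)
  lb <- ldm_backward_batch(ub$dx, fwd$ldm_cache)
  c(ub$grads, lb$grads)
}

stack_windows <- function(windows) {
  # windows: list of list(x = H x W x 1 array, mask = length-W 0/1 vector)
  H <- dim(windows[[1]]$x)[1]
  W <- dim(windows[[1]]$x)[2]
  B <- length(windows)
  x <- array(0, c(B * H, W, 1L))
  t <- matrix(0, B, W)
  for (b in seq_len(B)) {
    x[(b - 1L) * H + seq_len(H), , 1L] <- windows[[b]]$x[, , 1L]
    t[b, ] <- windows[[b]]$mask
  }
  list(x = x, t = t, H = H, B = B)
}

#' Train the detector on labelled windows
#'
#' Mini-batch Adam on the mean per-window dice loss. Windows whose target
#' mask is all zero are excluded (the dice formula gives them a constant
#' loss of 1 with a degenerate gradient). A seed-controlled fraction of the
#' windows is held out and the parameters with the best held-out loss are
#' returned (when `val_fraction` is 0, the final parameters are returned).
#' Training is deterministic given the seed.
#'
#' @param model A `qrs_detector` from [build_model()].
#' @param windows List of training windows, each a list with `x` (an
#'   H x W x 1 array at the scaled resolution, from [axis_transform()])
#'   and `mask` (length-W 0/1 target, from [decimate_mask()]).
#' @param config A [train_config()]; defaults to the model's.
#' @param quiet Suppress per-epoch progress?
#' @return The trained `qrs_detector`, with a `history` element: a tibble
#'   with columns `epoch`, `train_loss`, `val_loss`.
#' @export
train <- function(model, windows, config = NULL, quiet = TRUE) {
  stopifnot(inherits(model, "qrs_detector"))
  if (length(windows) == 0) stop("empty training set")
  config <- config %||% model$cfg$train
  keep <- vapply(windows, function(w) any(w$mask > 0), logical(1))
  windows <- windows[keep]
  if (length(windows) == 0) stop("no windows with a non-empty target mask")
  set.seed(config$seed)
  n <- length(windows)
  n_val <- floor(config$val_fraction * n)
  idx <- sample.int(n)
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- setdiff(idx, val_idx)
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, stats = model$stats)
  hist <- list()
  if (config$epochs == 0L) {
    model$history <- tibble::tibble(epoch = integer(), train_loss = numeric(),
                                    val_loss = numeric())
    return(model)
  }
  val_batch <- if (n_val > 0) stack_windows(windows[val_idx]) else NULL
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      bidx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      bt <- stack_windows(windows[bidx])
      fwd <- model_forward_train(model, bt$x, bt$H, bt$B, training = TRUE)
      model$stats <- fwd$stats
      dl <- dice_loss_batch(fwd$prob, bt$t, config$dice_smooth)
      if (!is.finite(dl$loss))
        stop("non-finite training loss at epoch ", ep)
      grads <- model_backward_train(fwd, dl$dp)
      upd <- adam_step(model$params, grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + dl$loss
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    val_loss <- NA_real_
    if (!is.null(val_batch)) {
      vf <- model_forward_train(model, val_batch$x, val_batch$H,
                                val_batch$B, training = FALSE)
      val_loss <- dice_loss_batch(vf$prob, val_batch$t,
                                  config$dice_smooth)$loss
      if (val_loss < best$loss)
        best <- list(loss = val_loss, params = model$params,
                     stats = model$stats)
    }
    hist[[ep]] <- c(epoch = ep, train_loss = ep_loss, val_loss = val_loss)
    if (!quiet)
      message(sprintf("epoch %3d  train %.4f  val %s", ep, ep_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
  }
  if (!is.null(val_batch) && is.finite(best$loss)) {
    model$params <- best$params
    model$stats <- best$stats
  }
  h <- do.call(rbind, hist)
  model$history <- tibble::tibble(epoch = as.integer(h[, "epoch"]),
                                  train_loss = h[, "train_loss"],
                                  val_loss = h[, "val_loss"])
  model
}
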