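# QRS detection module: a small 1-D U-Net over the distilled signal.
# Encoder: per level, `depth` conv units (same-padded conv -> BN -> leaky
# ReLU) then a parameter-free halving max-pool; the deepest level has no
# skip input. Decoder: parameter-free nearest-neighbour doubling (cropped
# to the paired pre-pool length), channel concatenation with the skip, then
# `depth` conv units. Head: 1x1 convolution to one channel + sigmoid, so
# input and output lengths agree for every input length.

#' U-Net hyperparameters
#'
#' @param filter_size Channels of every conv unit (default 3).
#' @param depth Conv units per side per level (default 3).
#' @param levels Index of the deepest level (default 2, i.e. three levels).
#' @param kernel_sizes Odd kernel width per level, level 0 first
#'   (default `c(11, 17, 13)`).
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(filter_size = 3, depth = 3, levels = 2,
                        kernel_sizes = c(11, 17, 13)) {
  stopifnot(filter_size >= 1, depth >= 1, levels >= 0,
            length(kernel_sizes) == levels + 1,
            all(kernel_sizes %% 2 == 1))
  structure(list(filter_size = as.integer(filter_size),
                 depth = as.integer(depth),
                 levels = as.integer(levels),
                 kernel_sizes = as.integer(kernel_sizes)),
            class = "unet_config")
}

unet_unit_prefixes <- function(cfg) {
  # ordered (prefix, kernel, cin, cout) for every conv unit plus the head
  f <- cfg$filter_size
  out <- list()
  for (l in 0:cfg$levels) {
    for (u in seq_len(cfg$depth)) {
      cin <- if (l == 0 && u == 1) 1L else f
      out[[length(out) + 1L]] <- list(
        prefix = sprintf("unet.enc.l%d.u%d", l, u),
        k = cfg$kernel_sizes[l + 1], cin = cin, cout = f)
    }
  }
  for (l in rev(seq_len(cfg$levels) - 1L)) {
    for (u in seq_len(cfg$depth)) {
      cin <- if (u == 1) 2L * f else f
      out[[length(out) + 1L]] <- list(
        prefix = sprintf("unet.dec.l%d.u%d", l, u),
        k = cfg$kernel_sizes[l + 1], cin = cin, cout = f)
    }
  }
  out[[length(out) + 1L]] <- list(prefix = "unet.head", k = 1L,
                                  cin = f, cout = 1L)
  out
}

unit_fwd <- function(x, params, stats, prefix, training, slope) {
  w <- params[[paste0(prefix, ".w")]]
  gamma <- params[[paste0(prefix, ".gamma")]]
  beta <- params[[paste0(prefix, ".beta")]]
  r <- cpp_unit_fwd(x, w, params[[paste0(prefix, ".b")]], gamma, beta,
                    stats[[paste0(prefix, ".rm")]],
                    stats[[paste0(prefix, ".rv")]], training, 0.1, 1e-5,
                    slope, dim(x), dim(w))
  list(out = r$out, rm = r$rm, rv = r$rv,
       cache = list(x = x, w = w, out = r$out, invstd = r$invstd,
                    gamma = gamma, beta = beta, training = training,
                    xdim = dim(x), prefix = prefix))
}

unit_bwd <- function(dout, cache, grads, slope) {
  r <- cpp_unit_bwd(dout, cache$out, cache$invstd, cache$gamma,
                    cache$beta, slope, cache$x, cache$w, cache$training,
                    cache$xdim, dim(cache$w))
  grads[[paste0(cache$prefix, ".w")]] <- r$dw
  grads[[paste0(cache$prefix, ".b")]] <- r$db
  grads[[paste0(cache$prefix, ".gamma")]] <- r$dgamma
  grads[[paste0(cache$prefix, ".beta")]] <- r$dbeta
  list(dx = r$dx, grads = grads)
}

unet_forward_batch <- function(s, params, stats, cfg, training = FALSE,
                               slope = 0.3) {
  # s: B x W matrix of distilled signals -> B x W probability matrix
  B <- nrow(s); W <- ncol(s)
  h <- array(s, c(B, W, 1L))
  caches <- list()
  skips <- list()
  pre_pool_w <- integer(cfg$levels)
  for (l in 0:cfg$levels) {
    for (u in seq_len(cfg$depth)) {
      r <- unit_fwd(h, params, stats, sprintf("unet.enc.l%d.u%d", l, u),
                    training, slope)
      stats[[sprintf("unet.enc.l%d.u%d.rm", l, u)]] <- r$rm
      stats[[sprintf("unet.enc.l%d.u%d.rv", l, u)]] <- r$rv
      caches[[length(caches) + 1L]] <- c(r$cache, list(type = "unit"))
      h <- r$out
    }
    if (l < cfg$levels) {
      skips[[l + 1L]] <- h
      pre_pool_w[l + 1L] <- dim(h)[2]
      p <- pool2_fwd(h)
      caches[[length(caches) + 1L]] <- c(p$cache, list(type = "pool",
                                                       level = l))
      h <- p$out
    }
  }
  for (l in rev(seq_len(cfg$levels) - 1L)) {
    up <- up2_fwd(h, pre_pool_w[l + 1L])
    caches[[length(caches) + 1L]] <- c(up$cache, list(type = "up"))
    h <- concat_c(up$out, skips[[l + 1L]])
    caches[[length(caches) + 1L]] <- list(type = "concat",
                                          c1 = dim(up$out)[3], level = l)
    for (u in seq_len(cfg$depth)) {
      r <- unit_fwd(h, params, stats, sprintf("unet.dec.l%d.u%d", l, u),
                    training, slope)
      stats[[sprintf("unet.dec.l%d.u%d.rm", l, u)]] <- r$rm
      stats[[sprintf("unet.dec.l%d.u%d.rv", l, u)]] <- r$rv
      caches[[length(caches) + 1L]] <- c(r$cache, list(type = "unit"))
      h <- r$out
    }
  }
  hd <- conv_fwd(h, params$unet.head.w, params$unet.head.b)
  caches[[length(caches) + 1L]] <- c(hd$cache, list(type = "head"))
  p <- sigmoid(hd$out)
  list(out = matrix(p, B, W), p = p, stats = stats,
       cache = list(ops = caches, slope = slope, B = B, W = W))
}

unet_backward_batch <- function(dp, cache, p) {
  # dp: B x W gradient on the probabilities; p: B x W x 1 sigmoid output
  slope <- cache$slope
  grads <- list()
  d <- array(dp, dim(p)) * p * (1 - p)
  # skip-connection gradients accumulate when their concat op is reached
  skip_grads <- list()
  for (i in rev(seq_along(cache$ops))) {
    op <- cache$ops[[i]]
    if (op$type == "head") {
      cv <- conv_bwd(d, op[c("x", "w")])
      grads$unet.head.w <- cv$dw
      grads$unet.head.b <- cv$db
      d <- cv$dx
    } else if (op$type == "unit") {
      r <- unit_bwd(d, op, grads, slope)
      grads <- r$grads
      d <- r$dx
    } else if (op$type == "concat") {
      c1 <- op$c1
      # the second concat input is the skip from this level's last encoder
      # unit; its gradient joins the main chain after that level's pool
      skip_grads[[as.character(op$level)]] <-
        d[, , (c1 + 1L):dim(d)[3], drop = FALSE]
      d <- d[, , seq_len(c1), drop = FALSE]
    } else if (op$type == "up") {
      d <- up2_bwd(d, op)
    } else if (op$type == "pool") {
      d <- pool2_bwd(d, op)
      sg <- skip_grads[[as.character(op$level)]]
      if (!is.null(sg)) d <- d + sg
    }
  }
  list(dx = matrix(d, cache$B, cache$W), grads = grads)
}
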