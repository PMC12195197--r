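# Low-level network primitives. Feature maps are numeric arrays of dim
# (R, W, C): R independent rows (batch x leads folded together, since every
# kernel has height 1 and never mixes leads), W samples, C channels.
# Each forward returns list(out, cache); each backward takes the incoming
# gradient plus the cache and returns the input gradient and parameter
# gradients. The convolution tap loops live in src/nn_kernels.cpp; the
# cheap elementwise/normalization pieces stay in R.

as_map <- function(x) {
  if (is.null(dim(x))) array(x, c(1L, length(x), 1L))
  else if (length(dim(x)) == 2) array(x, c(dim(x), 1L))
  else x
}

conv_fwd <- function(x, w, b) {
  stopifnot(dim(w)[2] == dim(x)[3], length(b) == dim(w)[3])
  out <- cpp_conv_fwd(x, w, b, dim(x), dim(w))
  list(out = out, cache = list(x = x, w = w))
}

conv_bwd <- function(dout, cache) {
  cpp_conv_bwd(cache$x, cache$w, dout, dim(cache$x), dim(cache$w))
}

dwconv_fwd <- function(x, w, b) {
  # depth-wise: one 1 x k kernel per channel, channels never mix
  stopifnot(ncol(w) == dim(x)[3], length(b) == dim(x)[3])
  out <- cpp_dwconv_fwd(x, w, b, dim(x))
  list(out = out, cache = list(x = x, w = w))
}

dwconv_bwd <- function(dout, cache) {
  cpp_dwconv_bwd(cache$x, cache$w, dout, dim(cache$x))
}

bn_fwd <- function(x, gamma, beta, rm, rv, training, momentum = 0.1,
                   eps = 1e-5) {
  r <- cpp_bn_fwd(x, gamma, beta, rm, rv, training, momentum, eps, dim(x))
  list(out = r$out, rm = r$rm, rv = r$rv,
       cache = list(xhat = r$xhat, invstd = r$invstd, gamma = gamma,
                    dims = dim(x), training = training))
}

bn_bwd <- function(dout, cache) {
  cpp_bn_bwd(dout, cache$xhat, cache$invstd, cache$gamma, cache$training,
             cache$dims)
}

#' Leaky rectified linear unit
#'
#' Elementwise `max(0, x) + slope * min(0, x)`: the positive part passes
#' unchanged and the negative part is multiplied by the slope (0.3 here).
#'
#' @param x Numeric vector or array.
#' @param slope Negative-side slope (default 0.3).
#' @return Same shape as `x`.
#' @export
leaky_relu <- function(x, slope = 0.3) {
  if (!is.double(x)) storage.mode(x) <- "double"
  cpp_lrelu(x, slope)
}

lrelu_bwd <- function(dout, x, slope = 0.3) {
  cpp_lrelu_bwd(dout, x, slope)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

pool2_fwd <- function(x) {
  # halving max-pool along W; odd lengths are right-padded by replication
  d <- dim(x); W <- d[2]
  padded <- W %% 2L == 1L
  if (padded) {
    x2 <- array(0, c(d[1], W + 1L, d[3]))
    x2[, seq_len(W), ] <- x
    x2[, W + 1L, ] <- x[, W, ]
    x <- x2
  }
  odd <- x[, seq(1L, dim(x)[2], 2L), , drop = FALSE]
  eve <- x[, seq(2L, dim(x)[2], 2L), , drop = FALSE]
  take_odd <- odd >= eve
  list(out = pmax(odd, eve),
       cache = list(take_odd = take_odd, in_w = W, padded = padded))
}

pool2_bwd <- function(dout, cache) {
  d <- dim(dout)
  Wp <- 2L * d[2]
  dx <- array(0, c(d[1], Wp, d[3]))
  dx[, seq(1L, Wp, 2L), ] <- dout * cache$take_odd
  dx[, seq(2L, Wp, 2L), ] <- dout * !cache$take_odd
  if (cache$padded) {
    dx[, cache$in_w, ] <- dx[, cache$in_w, , drop = FALSE] +
      dx[, Wp, , drop = FALSE]
    dx <- dx[, seq_len(cache$in_w), , drop = FALSE]
  }
  dx
}

up2_fwd <- function(x, target_w) {
  # nearest-neighbour doubling along W, cropped to the paired pre-pool width
  d <- dim(x)
  idx <- rep(seq_len(d[2]), each = 2L)[seq_len(target_w)]
  list(out = x[, idx, , drop = FALSE],
       cache = list(in_w = d[2], target_w = target_w))
}

up2_bwd <- function(dout, cache) {
  d <- dim(dout)
  tw <- cache$target_w
  dx <- array(0, c(d[1], cache$in_w, d[3]))
  odd <- dout[, seq(1L, tw, 2L), , drop = FALSE]
  dx[, seq_len(dim(odd)[2]), ] <- odd
  if (tw >= 2L) {
    eve <- dout[, seq(2L, tw, 2L), , drop = FALSE]
    ne <- dim(eve)[2]
    dx[, seq_len(ne), ] <- dx[, seq_len(ne), , drop = FALSE] + eve
  }
  dx
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:2] == db[1:2]))
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}
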