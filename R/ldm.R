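# Leads-distillation module (LDM): per-sample attention over leads.
# Pipeline: 2D conv unit (13 filters, 1x11) -> depth-wise separable conv
# unit -> 1x11 squeeze conv to one channel + sigmoid (raw weight map A) ->
# column-wise softmax across leads (A') -> weighted column sum (distilled
# signal). Every kernel has height 1, so the module works for any number of
# leads without reconfiguration.

#' LDM hyperparameters
#'
#' @param n_filters Channels of the feature-extraction units (default 13).
#' @param kernel_width Width of the 1 x m kernels (default 11).
#' @param squeeze_kernel Width of the channel-squeeze conv (default 11).
#' @param lrelu_slope Negative slope of the leaky ReLU (default 0.3).
#' @return A list of class `ldm_config`.
#' @export
ldm_config <- function(n_filters = 13, kernel_width = 11, squeeze_kernel = 11,
                       lrelu_slope = 0.3) {
  stopifnot(n_filters >= 1, kernel_width %% 2 == 1, squeeze_kernel %% 2 == 1)
  structure(list(n_filters = as.integer(n_filters),
                 kernel_width = as.integer(kernel_width),
                 squeeze_kernel = as.integer(squeeze_kernel),
                 lrelu_slope = lrelu_slope),
            class = "ldm_config")
}

# ---- column softmax / distillation (matrix surface, used by the module
# and directly testable) ----

#' Column-wise softmax across leads
#'
#' Normalizes a raw H x W weight matrix so that every column (one sample
#' instant across all leads) sums to one:
#' `a'[i, j] = exp(a[i, j]) / sum_k exp(a[k, j])`. The per-column maximum is
#' subtracted before exponentiation for overflow safety, which leaves the
#' result mathematically unchanged. With a single lead (H = 1) every entry
#' is exactly 1.
#'
#' @param A Numeric H x W matrix (or vector treated as one row).
#' @return H x W matrix with unit column sums.
#' @export
column_softmax <- function(A) {
  if (is.vector(A)) A <- matrix(A, nrow = 1)
  H <- nrow(A)
  if (H == 1L) return(matrix(1, 1L, ncol(A)))
  mx <- A[1, ]
  for (h in 2:H) mx <- pmax(mx, A[h, ])
  e <- exp(A - matrix(mx, H, ncol(A), byrow = TRUE))
  e / matrix(colSums(e), H, ncol(A), byrow = TRUE)
}

#' Collapse a multi-lead map with a normalized weight map
#'
#' The distilled signal: `s[j] = sum_i X[i, j] * A'[i, j]`, a per-column
#' convex combination of the lead values (A' columns sum to one).
#'
#' @param X Numeric H x W lead matrix.
#' @param Aprime Normalized weight matrix of identical shape.
#' @return Numeric vector of length W.
#' @export
distill_signal <- function(X, Aprime) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (is.vector(Aprime)) Aprime <- matrix(Aprime, nrow = 1)
  if (!all(dim(X) == dim(Aprime))) stop("X and Aprime shapes disagree")
  colSums(X * Aprime)
}

# ---- functional single-map surface (eval-mode building blocks) ----

#' Convolution unit: 2D convolution, batch norm, leaky ReLU
#'
#' One feature-extraction unit on an H x W x C map: a "same"-padded
#' convolution with 1 x m kernels (height 1, so leads never mix), batch
#' normalization and a leaky ReLU. This functional form runs in evaluation
#' mode with explicit normalization statistics (defaults mean 0, variance 1,
#' scale 1, shift 0, i.e. BN reduced to identity up to its numerical
#' epsilon); inside a fitted model the learned running statistics are used.
#'
#' @param x Numeric array H x W x C (a matrix is treated as H x W x 1).
#' @param kernel Numeric array k x C x N of kernel weights.
#' @param bias Numeric vector of N biases.
#' @param bn_scale,bn_shift,bn_mean,bn_var Per-channel BN parameters.
#' @param slope Leaky-ReLU negative slope.
#' @return Numeric array H x W x N.
#' @export
conv_unit <- function(x, kernel, bias, bn_scale = NULL, bn_shift = NULL,
                      bn_mean = NULL, bn_var = NULL, slope = 0.3) {
  x <- as_map(x)
  n <- dim(kernel)[3]
  if (is.null(bn_scale)) bn_scale <- rep(1, n)
  if (is.null(bn_shift)) bn_shift <- rep(0, n)
  if (is.null(bn_mean)) bn_mean <- rep(0, n)
  if (is.null(bn_var)) bn_var <- rep(1, n)
  h <- conv_fwd(x, kernel, bias)$out
  h <- bn_fwd(h, bn_scale, bn_shift, bn_mean, bn_var, training = FALSE)$out
  leaky_relu(h, slope)
}

#' Depth-wise separable convolution unit
#'
#' A depth-wise 1 x m convolution (one kernel per channel; Eq.-style
#' `y_i = w_i * z_i + b_i`), batch norm and leaky ReLU, followed by a
#' point-wise 1 x 1 convolution unit mixing the channels. Runs in
#' evaluation mode like [conv_unit()].
#'
#' @param x Numeric array H x W x N.
#' @param dw_kernel k x N matrix of depth-wise kernels.
#' @param dw_bias Depth-wise biases (length N).
#' @param pw_kernel 1 x N x N array of point-wise weights.
#' @param pw_bias Point-wise biases (length N).
#' @param slope Leaky-ReLU negative slope.
#' @return Numeric array H x W x N.
#' @export
ds_conv_unit <- function(x, dw_kernel, dw_bias, pw_kernel, pw_bias,
                         slope = 0.3) {
  x <- as_map(x)
  if (dim(x)[3] != ncol(dw_kernel))
    stop("channel count does not match depth-wise kernels")
  n <- ncol(dw_kernel)
  h <- dwconv_fwd(x, dw_kernel, dw_bias)$out
  h <- bn_fwd(h, rep(1, n), rep(0, n), rep(0, n), rep(1, n), FALSE)$out
  h <- leaky_relu(h, slope)
  conv_unit(h, pw_kernel, pw_bias, slope = slope)
}

#' Squeeze a multi-channel map to a raw weight map
#'
#' A 1 x m convolution from N channels to one, followed by a sigmoid, so
#' every entry of the resulting H x W map lies strictly in (0, 1).
#'
#' @param x Numeric array H x W x N.
#' @param kernel k x N x 1 array of weights.
#' @param bias Scalar bias.
#' @return H x W matrix of raw (pre-softmax) weights.
#' @export
weight_map <- function(x, kernel, bias) {
  x <- as_map(x)
  a <- conv_fwd(x, kernel, bias)$out
  matrix(sigmoid(a), dim(x)[1], dim(x)[2])
}

# ---- batched module forward/backward over the flat parameter list ----

ldm_forward_batch <- function(x, params, stats, H, B, training = FALSE,
                              slope = 0.3, single = TRUE,
                              want_weights = FALSE) {
  W <- dim(x)[2]
  f <- cpp_ldm_chain_fwd(x, params, stats, H, B, W, training, slope,
                         single, want_weights)
  stats$ldm.cu.rm <- f$rm1; stats$ldm.cu.rv <- f$rv1
  stats$ldm.dw.rm <- f$rm2; stats$ldm.dw.rv <- f$rv2
  stats$ldm.pw.rm <- f$rm3; stats$ldm.pw.rv <- f$rv3
  list(out = f$s, weights_raw = f$a, stats = stats,
       cache = list(handle = f$handle, params = params,
                    training = training, slope = slope, single = single))
}

ldm_backward_batch <- function(ds, cache) {
  g <- cpp_ldm_chain_bwd(ds, cache$params, cache$handle, cache$training,
                         cache$slope, cache$single)
  list(grads = g)
}

#' Run the leads-distillation module of a detector
#'
#' Applies the fitted LDM to one H x W x 1 feature map (any H, including
#' H = 1, where the normalized weights are identically 1 and the distilled
#' signal is the single lead unchanged) and returns the distilled signal
#' together with the attention weights.
#'
#' @param model A `qrs_detector` from [build_model()].
#' @param x H x W x 1 array from [axis_transform()] (a leads x W matrix is
#'   accepted).
#' @return List with `distilled` (length-W vector), `weights` (H x W
#'   normalized map, columns sum to 1) and `weights_raw` (H x W sigmoid
#'   output in (0, 1)).
#' @export
ldm_forward <- function(model, x) {
  stopifnot(inherits(model, "qrs_detector"))
  x <- as_map(x)
  if (any(!is.finite(x))) stop("non-finite values in input")
  H <- dim(x)[1]
  f <- ldm_forward_batch(x, model$params, model$stats, H = H, B = 1L,
                         training = FALSE, slope = model$cfg$ldm$lrelu_slope,
                         single = FALSE, want_weights = TRUE)
  raw <- matrix(f$weights_raw, H, dim(x)[2])
  list(distilled = as.numeric(f$out),
       weights = column_softmax(raw),
       weights_raw = raw)
}
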