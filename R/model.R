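# Model assembly: flat named parameter/statistics lists for the LDM +
# U-Net detector, seeded initialization, parameter accounting and the
# eval-mode forward pass.

#' Full detector configuration
#'
#' Collects every tunable of the detector: module hyperparameters, the
#' scaling factor, the pass band, the training settings and the
#' post-processing thresholds.
#'
#' @param ldm An [ldm_config()].
#' @param unet A [unet_config()].
#' @param train A [train_config()].
#' @param band Band-pass edges in Hz (default `c(1, 40)`).
#' @param threshold Probability binarization threshold (default 0.5).
#' @param min_qrs_ms Minimum detected-region width in ms (default 40).
#' @param match_tol_ms Width of the beat-matching region in ms, centered on
#'   the reference annotation (default 75, i.e. +/- 37.5 ms).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(ldm = ldm_config(), unet = unet_config(),
                            train = train_config(), band = c(1, 40),
                            threshold = 0.5, min_qrs_ms = 40,
                            match_tol_ms = 75) {
  structure(list(ldm = ldm, unet = unet, train = train, band = band,
                 threshold = threshold, min_qrs_ms = min_qrs_ms,
                 match_tol_ms = match_tol_ms),
            class = "detector_config")
}

kaiming_uniform <- function(n, fan_in, slope = 0.3) {
  gain <- sqrt(2 / (1 + slope^2))
  lim <- gain * sqrt(3 / fan_in)
  stats::runif(n, -lim, lim)
}

init_conv <- function(k, cin, cout, slope = 0.3) {
  fan_in <- k * cin
  list(w = array(kaiming_uniform(k * cin * cout, fan_in, slope),
                 c(k, cin, cout)),
       b = stats::runif(cout, -1 / sqrt(fan_in), 1 / sqrt(fan_in)))
}

add_bn <- function(params, stats, prefix, c) {
  params[[paste0(prefix, ".gamma")]] <- rep(1, c)
  params[[paste0(prefix, ".beta")]] <- rep(0, c)
  stats[[paste0(prefix, ".rm")]] <- rep(0, c)
  stats[[paste0(prefix, ".rv")]] <- rep(1, c)
  list(params = params, stats = stats)
}

#' Build a QRS detector
#'
#' Instantiates the leads-distillation module and the U-Net with
#' seed-controlled Kaiming-style uniform fan-in initialization (BN scale 1,
#' shift 0, running statistics mean 0 / variance 1). The architecture is
#' lead-count agnostic: the same model runs on 1 to 12 (or more) leads.
#'
#' @param ldm An [ldm_config()].
#' @param unet A [unet_config()].
#' @param config Optionally a full [detector_config()] (overrides `ldm` and
#'   `unet`).
#' @param seed Integer seed for the initialization.
#' @return An object of class `qrs_detector` with elements `params`
#'   (trainable arrays), `stats` (BN running statistics) and `cfg`.
#' @export
build_model <- function(ldm = ldm_config(), unet = unet_config(),
                        config = NULL, seed = 0) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "detector_config"))
    ldm <- config$ldm
    unet <- config$unet
  } else {
    config <- detector_config(ldm = ldm, unet = unet)
  }
  set.seed(seed)
  slope <- ldm$lrelu_slope
  n <- ldm$n_filters
  params <- list()
  stats <- list()
  cv <- init_conv(ldm$kernel_width, 1L, n, slope)
  params$ldm.cu.w <- cv$w; params$ldm.cu.b <- cv$b
  r <- add_bn(params, stats, "ldm.cu", n); params <- r$params; stats <- r$stats
  params$ldm.dw.w <- matrix(kaiming_uniform(ldm$kernel_width * n,
                                            ldm$kernel_width, slope),
                            ldm$kernel_width, n)
  params$ldm.dw.b <- stats::runif(n, -1 / sqrt(ldm$kernel_width),
                                  1 / sqrt(ldm$kernel_width))
  r <- add_bn(params, stats, "ldm.dw", n); params <- r$params; stats <- r$stats
  cv <- init_conv(1L, n, n, slope)
  params$ldm.pw.w <- cv$w; params$ldm.pw.b <- cv$b
  r <- add_bn(params, stats, "ldm.pw", n); params <- r$params; stats <- r$stats
  cv <- init_conv(ldm$squeeze_kernel, n, 1L, slope)
  params$ldm.sq.w <- cv$w; params$ldm.sq.b <- cv$b
  for (u in unet_unit_prefixes(unet)) {
    cv <- init_conv(u$k, u$cin, u$cout, slope)
    params[[paste0(u$prefix, ".w")]] <- cv$w
    params[[paste0(u$prefix, ".b")]] <- cv$b
    if (u$prefix != "unet.head") {
      r <- add_bn(params, stats, u$prefix, u$cout)
      params <- r$params; stats <- r$stats
    }
  }
  structure(list(params = params, stats = stats, cfg = config),
            class = "qrs_detector")
}

#' Count trainable parameters
#'
#' Sums every trainable scalar of the detector: convolution weights and
#' biases plus batch-norm scale and shift. BN running statistics are
#' buffers, not parameters, and are excluded. The count is independent of
#' the input length and of the number of leads.
#'
#' @param model A `qrs_detector` (or any flat list of parameter arrays).
#' @return Integer number of trainable scalars.
#' @export
count_parameters <- function(model) {
  params <- if (inherits(model, "qrs_detector")) model$params else model
  sum(vapply(params, length, integer(1)))
}

#' @export
print.qrs_detector <- function(x, ...) {
  cat(sprintf(
    "<qrs_detector> %d trainable parameters (LDM %d filters, U-Net %d levels)\n",
    count_parameters(x), x$cfg$ldm$n_filters, x$cfg$unet$levels + 1L))
  invisible(x)
}

#' Segment QRS probabilities from distilled signals
#'
#' Runs the U-Net in evaluation mode (BN running statistics, deterministic)
#' on one or more distilled signals. Output length equals input length for
#' every input length, including lengths not divisible by a power of two
#' (odd intermediate lengths are right-padded by replication before pooling
#' and cropped after up-sampling).
#'
#' @param model A `qrs_detector`.
#' @param s Numeric vector (one distilled signal) or B x W matrix.
#' @return Probability vector (or matrix matching `s`) with values in
#'   `[0, 1]`.
#' @export
detect_probabilities <- function(model, s) {
  stopifnot(inherits(model, "qrs_detector"))
  vec <- is.vector(s)
  if (vec) s <- matrix(s, nrow = 1)
  if (length(s) == 0) stop("empty input")
  if (any(!is.finite(s))) stop("non-finite values in input")
  out <- unet_forward_batch(s, model$params, model$stats, model$cfg$unet,
                            training = FALSE,
                            slope = model$cfg$ldm$lrelu_slope)$out
  if (vec) as.numeric(out) else out
}

#' Save / load a detector checkpoint
#'
#' The checkpoint holds the trainable parameters, the BN running statistics
#' and the full configuration.
#'
#' @param model A `qrs_detector`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the restored `qrs_detector`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "qrs_detector"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "qrs_detector"))
  model
}
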