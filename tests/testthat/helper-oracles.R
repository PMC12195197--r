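# Independent reference implementations used as oracles. These are written
# as plain loops, deliberately sharing no code with the package internals.

# direct "same"-padded convolution of an H x W x Cin array with
# (k, Cin, Cout) kernels
oracle_conv <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
  k <- dim(w)[1]; cout <- dim(w)[3]
  pad <- (k - 1) %/% 2
  y <- array(0, c(H, W, cout))
  for (co in seq_len(cout)) for (h in seq_len(H)) for (j in seq_len(W)) {
    acc <- b[co]
    for (ci in seq_len(cin)) for (t in seq_len(k)) {
      jj <- j + t - 1 - pad
      if (jj >= 1 && jj <= W) acc <- acc + x[h, jj, ci] * w[t, ci, co]
    }
    y[h, j, co] <- acc
  }
  y
}

oracle_bn_eval <- function(x, scale, shift, mean, var, eps = 1e-5) {
  y <- x
  for (c in seq_len(dim(x)[3]))
    y[, , c] <- scale[c] * (x[, , c] - mean[c]) / sqrt(var[c] + eps) + shift[c]
  y
}

oracle_lrelu <- function(x, slope = 0.3) ifelse(x > 0, x, slope * x)

# full straight-loop LDM on one H x W x 1 map given a model's parameters
# and running statistics (evaluation mode)
oracle_ldm <- function(model, x) {
  p <- model$params; s <- model$stats
  slope <- model$cfg$ldm$lrelu_slope
  z <- oracle_lrelu(oracle_bn_eval(oracle_conv(x, p$ldm.cu.w, p$ldm.cu.b),
                                   p$ldm.cu.gamma, p$ldm.cu.beta,
                                   s$ldm.cu.rm, s$ldm.cu.rv), slope)
  # depth-wise conv channel by channel
  k <- nrow(p$ldm.dw.w); pad <- (k - 1) %/% 2
  H <- dim(x)[1]; W <- dim(x)[2]; n <- ncol(p$ldm.dw.w)
  y <- array(0, dim(z))
  for (c in seq_len(n)) for (h in seq_len(H)) for (j in seq_len(W)) {
    acc <- p$ldm.dw.b[c]
    for (t in seq_len(k)) {
      jj <- j + t - 1 - pad
      if (jj >= 1 && jj <= W) acc <- acc + z[h, jj, c] * p$ldm.dw.w[t, c]
    }
    y[h, j, c] <- acc
  }
  y <- oracle_lrelu(oracle_bn_eval(y, p$ldm.dw.gamma, p$ldm.dw.beta,
                                   s$ldm.dw.rm, s$ldm.dw.rv), slope)
  yp <- oracle_lrelu(oracle_bn_eval(oracle_conv(y, p$ldm.pw.w, p$ldm.pw.b),
                                    p$ldm.pw.gamma, p$ldm.pw.beta,
                                    s$ldm.pw.rm, s$ldm.pw.rv), slope)
  q <- oracle_conv(yp, p$ldm.sq.w, p$ldm.sq.b)
  a <- 1 / (1 + exp(-q[, , 1, drop = FALSE]))
  a <- matrix(a, H, W)
  ap <- matrix(0, H, W)
  for (j in seq_len(W)) {
    e <- exp(a[, j] - max(a[, j]))
    ap[, j] <- e / sum(e)
  }
  xs <- matrix(x, H, W)
  list(distilled = colSums(xs * ap), weights = ap, weights_raw = a)
}

oracle_dice <- function(p, t, delta = 1e-5) {
  2 * sum(p * t) / (sum(p * p) + sum(t * t) + delta)
}

# maximum-cardinality matching between sorted detections and references
# within +/- tol samples, by memoized two-pointer dynamic programming
oracle_max_matching <- function(detected, reference, tol) {
  nd <- length(detected); nr <- length(reference)
  memo <- matrix(NA_integer_, nd + 1, nr + 1)
  rec <- function(i, j) {
    if (i > nd || j > nr) return(0L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- max(rec(i + 1L, j), rec(i, j + 1L))
    if (abs(detected[i] - reference[j]) <= tol)
      best <- max(best, 1L + rec(i + 1L, j + 1L))
    memo[i, j] <<- best
    best
  }
  rec(1L, 1L)
}

# maximal runs of ones via rle-free scanning
oracle_runs <- function(mask) {
  runs <- list()
  start <- NA
  for (i in seq_along(mask)) {
    if (mask[i] == 1 && is.na(start)) start <- i
    if ((mask[i] == 0 || i == length(mask)) && !is.na(start)) {
      end <- if (mask[i] == 1) i else i - 1
      runs[[length(runs) + 1]] <- c(start - 1, end - 1)  # 0-based
      start <- NA
    }
  }
  runs
}

# FFT amplitude of a pure tone after passing a 1-D operation
tone_gain <- function(op, freq, fs, n = 4 * fs) {
  t <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * freq * t)
  y <- op(x)
  bin <- round(freq * n / fs) + 1
  Mod(stats::fft(y))[bin] / Mod(stats::fft(x))[bin]
}

# small labelled synthetic windows for training smoke tests
make_tiny_windows <- function(n = 12, seed = 0, n_leads = 1, factor = 0.2,
                              noise_rms = 0.01, fake_leads = 0) {
  recs <- lapply(seq_len(n %/% 3) + seed, function(s)
    generate_record(synth_config(n_leads = n_leads, fs = 250,
                                 duration = 30, noise_rms = noise_rms,
                                 baseline_amp = 0.02,
                                 fake_qrs_leads = fake_leads, seed = s)))
  unlist(lapply(recs, prepare_training_windows, factor = factor),
         recursive = FALSE)
}
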