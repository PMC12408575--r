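## Conformer R-peak saliency network.
##
## A conformer interleaves feed-forward, multi-head self-attention and
## convolution modules; here it regresses, for every sample of a Doppler
## waveform window, a saliency value that is 1 at R-peaks and ramps linearly
## to 0 within a half-width, the classic triangular target for peak
## localization. Peaks are then read off the saliency trace with a
## threshold + refractory-period picker.

#' Conformer configuration
#'
#' Defaults are the published detector settings: five conformer blocks of
#' model dimension 30, three attention heads, convolution kernel 31,
#' feed-forward dimension 512, batch size 512, 300 epochs, Adam with
#' learning rate 1e-4 and MSE loss.
#'
#' @param n_blocks,model_dim,n_heads,conv_kernel,ffn_dim architecture sizes;
#'   `model_dim` must be divisible by `n_heads` and `conv_kernel` odd.
#' @param batch_size,epochs,lr training hyperparameters.
#' @param window_len training window length in samples (at 250 Hz).
#' @param overlap_fraction sliding-window overlap in \[0, 1).
#' @param half_width triangular target half-width in samples (+-48 ms at
#'   250 Hz, covering typical seismocardiogram peak jitter).
#' @return object of class `peaknet_config`.
#' @export
peaknet_config <- function(n_blocks = 5L, model_dim = 30L, n_heads = 3L,
                           conv_kernel = 31L, ffn_dim = 512L,
                           batch_size = 512L, epochs = 300L, lr = 1e-4,
                           window_len = 512L, overlap_fraction = 0.5,
                           half_width = 12L) {
  if (model_dim %% n_heads != 0L) stop_beat("model_dim must be divisible by n_heads")
  if (conv_kernel %% 2L != 1L) stop_beat("conv_kernel must be odd")
  structure(as.list(environment()), class = "peaknet_config")
}

#' Triangular peak-saliency target
#'
#' Value 1 at each annotated peak, decaying linearly to 0 over `half_width`
#' samples; overlapping ramps are resolved by elementwise maximum.
#'
#' @param peaks sorted 1-based peak indices within `[1, length]`.
#' @param length trace length in samples.
#' @param half_width ramp half-width in samples (> 0).
#' @return numeric vector in \[0, 1\].
#' @export
encode_triangular <- function(peaks, length, half_width = 12L) {
  if (half_width <= 0) stop_beat("half_width must be positive")
  y <- numeric(length)
  for (p in peaks) {
    i <- max(1L, p - half_width):min(length, p + half_width)
    y[i] <- pmax(y[i], 1 - abs(i - p) / half_width)
  }
  y
}

#' Slice a recording into standardized training windows
#'
#' Sliding windows with hop `window_len * (1 - overlap_fraction)`; each input
#' window is standardized to zero mean and unit variance, targets are sliced
#' identically (unscaled).
#'
#' @param x waveform vector.
#' @param target saliency target of the same length.
#' @param window_len window length in samples.
#' @param overlap_fraction overlap in \[0, 1).
#' @return list with matrices `x` and `y`, one row per window.
#' @export
make_training_windows <- function(x, target, window_len, overlap_fraction = 0.5) {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop_beat("overlap_fraction must be in [0, 1)")
  if (window_len > length(x)) stop_beat("window_len exceeds signal length")
  stopifnot(length(target) == length(x))
  hop <- max(1L, round(window_len * (1 - overlap_fraction)))
  starts <- seq(1L, length(x) - window_len + 1L, by = hop)
  xs <- t(vapply(starts, function(s) x[s:(s + window_len - 1L)], numeric(window_len)))
  ys <- t(vapply(starts, function(s) target[s:(s + window_len - 1L)], numeric(window_len)))
  xs <- t(apply(xs, 1L, function(r) {
    s <- stats::sd(r)
    (r - mean(r)) / if (s > 1e-12) s else 1
  }))
  list(x = xs, y = ys, starts = starts)
}

## ---- model -----------------------------------------------------------------

sinusoidal_pe <- function(T, d) {
  pos <- seq_len(T) - 1L
  pe <- matrix(0, T, d)
  for (i in seq_len(ceiling(d / 2))) {
    w <- 1 / 10000^(2 * (i - 1) / d)
    pe[, 2 * i - 1] <- sin(pos * w)
    if (2 * i <= d) pe[, 2 * i] <- cos(pos * w)
  }
  pe
}

init_peaknet <- function(cfg) {
  d <- cfg$model_dim
  block <- function() list(
    ln1 = init_layernorm(d),
    ffn1 = list(l1 = init_linear(d, cfg$ffn_dim), l2 = init_linear(cfg$ffn_dim, d)),
    ln2 = init_layernorm(d),
    att = list(Wq = init_mat(d, d), bq = numeric(d), Wk = init_mat(d, d),
               bk = numeric(d), Wv = init_mat(d, d), bv = numeric(d),
               Wo = init_mat(d, d), bo = numeric(d)),
    ln3 = init_layernorm(d),
    conv = list(pw1 = init_linear(d, 2L * d),
                dw = list(W = init_mat(cfg$conv_kernel, d, sqrt(1 / cfg$conv_kernel)),
                          b = numeric(d)),
                lnc = init_layernorm(d),
                pw2 = init_linear(d, d)),
    ln4 = init_layernorm(d),
    ffn2 = list(l1 = init_linear(d, cfg$ffn_dim), l2 = init_linear(cfg$ffn_dim, d)),
    ln5 = init_layernorm(d))
  list(embed = init_linear(1L, d, 1),
       blocks = lapply(seq_len(cfg$n_blocks), function(i) block()),
       head = init_linear(d, 1L))
}

ffn_fwd <- function(x, p) {
  c1 <- linear_fwd(x, p$l1); a <- swish_fwd(c1$y); c2 <- linear_fwd(a$y, p$l2)
  list(y = c2$y, c1 = c1, a = a, c2 = c2)
}
ffn_bwd <- function(cache, p, g) {
  b2 <- linear_bwd(cache$c2, p$l2, g)
  ga <- swish_bwd(cache$a, b2$dx)
  b1 <- linear_bwd(cache$c1, p$l1, ga)
  list(dx = b1$dx, dp = list(l1 = b1$dp, l2 = b2$dp))
}

# attention over each sequence of the stacked batch
mhsa_batch_fwd <- function(x, p, n_heads, B, T) {
  y <- matrix(0, nrow(x), ncol(x))
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    caches[[b]] <- mhsa_fwd(x[rows, , drop = FALSE], p, n_heads)
    y[rows, ] <- caches[[b]]$y
  }
  list(y = y, caches = caches, B = B, T = T)
}
mhsa_batch_bwd <- function(cache, p, g) {
  dx <- matrix(0, nrow(g), ncol(g))
  dp <- NULL
  for (b in seq_len(cache$B)) {
    rows <- ((b - 1L) * cache$T + 1L):(b * cache$T)
    bb <- mhsa_bwd(cache$caches[[b]], p, g[rows, , drop = FALSE])
    dx[rows, ] <- bb$dx
    dp <- if (is.null(dp)) bb$dp else add_grads(dp, bb$dp)
  }
  list(dx = dx, dp = dp)
}

conv_module_fwd <- function(x, p, B, T) {
  c1 <- linear_fwd(x, p$pw1)
  d <- ncol(x)
  a <- c1$y[, seq_len(d), drop = FALSE]
  bgate <- c1$y[, d + seq_len(d), drop = FALSE]
  sg <- sigmoid(bgate)
  glu <- a * sg
  dw <- dwconv1d_fwd(glu, p$dw, B, T)
  ln <- layernorm_fwd(dw$y, p$lnc)
  sw <- swish_fwd(ln$y)
  c2 <- linear_fwd(sw$y, p$pw2)
  list(y = c2$y, c1 = c1, a = a, sg = sg, dw = dw, ln = ln, sw = sw, c2 = c2)
}
conv_module_bwd <- function(cache, p, g) {
  b2 <- linear_bwd(cache$c2, p$pw2, g)
  gsw <- swish_bwd(cache$sw, b2$dx)
  bln <- layernorm_bwd(cache$ln, p$lnc, gsw)
  bdw <- dwconv1d_bwd(cache$dw, p$dw, bln$dx)
  da <- bdw$dx * cache$sg
  dgate <- bdw$dx * cache$a * cache$sg * (1 - cache$sg)
  b1 <- linear_bwd(cache$c1, p$pw1, cbind(da, dgate))
  list(dx = b1$dx, dp = list(pw1 = b1$dp, dw = bdw$dp, lnc = bln$dp, pw2 = b2$dp))
}

block_fwd <- function(x, p, cfg, B, T) {
  l1 <- layernorm_fwd(x, p$ln1); f1 <- ffn_fwd(l1$y, p$ffn1)
  h1 <- x + 0.5 * f1$y
  l2 <- layernorm_fwd(h1, p$ln2); at <- mhsa_batch_fwd(l2$y, p$att, cfg$n_heads, B, T)
  h2 <- h1 + at$y
  l3 <- layernorm_fwd(h2, p$ln3); cv <- conv_module_fwd(l3$y, p$conv, B, T)
  h3 <- h2 + cv$y
  l4 <- layernorm_fwd(h3, p$ln4); f2 <- ffn_fwd(l4$y, p$ffn2)
  h4 <- h3 + 0.5 * f2$y
  l5 <- layernorm_fwd(h4, p$ln5)
  list(y = l5$y, l1 = l1, f1 = f1, l2 = l2, at = at, l3 = l3, cv = cv,
       l4 = l4, f2 = f2, l5 = l5)
}
block_bwd <- function(cache, p, cfg, g) {
  b5 <- layernorm_bwd(cache$l5, p$ln5, g); g4 <- b5$dx
  bf2 <- ffn_bwd(cache$f2, p$ffn2, 0.5 * g4)
  b4 <- layernorm_bwd(cache$l4, p$ln4, bf2$dx); g3 <- g4 + b4$dx
  bcv <- conv_module_bwd(cache$cv, p$conv, g3)
  b3 <- layernorm_bwd(cache$l3, p$ln3, bcv$dx); g2 <- g3 + b3$dx
  bat <- mhsa_batch_bwd(cache$at, p$att, g2)
  b2 <- layernorm_bwd(cache$l2, p$ln2, bat$dx); g1 <- g2 + b2$dx
  bf1 <- ffn_bwd(cache$f1, p$ffn1, 0.5 * g1)
  b1 <- layernorm_bwd(cache$l1, p$ln1, bf1$dx); g0 <- g1 + b1$dx
  list(dx = g0,
       dp = list(ln1 = b1$dp, ffn1 = bf1$dp, ln2 = b2$dp, att = bat$dp,
                 ln3 = b3$dp, conv = bcv$dp, ln4 = b4$dp, ffn2 = bf2$dp,
                 ln5 = b5$dp))
}

peaknet_fwd <- function(params, x, cfg, B, T) {
  em <- linear_fwd(x, params$embed)
  pe <- sinusoidal_pe(T, cfg$model_dim)
  h <- em$y + pe[rep(seq_len(T), times = B), ]
  bl <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    bl[[i]] <- block_fwd(h, params$blocks[[i]], cfg, B, T)
    h <- bl[[i]]$y
  }
  hd <- linear_fwd(h, params$head)
  sg <- sigmoid_fwd(hd$y)
  list(y = sg$y, em = em, bl = bl, hd = hd, sg = sg)
}
peaknet_bwd <- function(params, cache, cfg, g) {
  gh <- sigmoid_bwd(cache$sg, g)
  bh <- linear_bwd(cache$hd, params$head, gh)
  gcur <- bh$dx
  dblocks <- vector("list", cfg$n_blocks)
  for (i in rev(seq_len(cfg$n_blocks))) {
    bb <- block_bwd(cache$bl[[i]], params$blocks[[i]], cfg, gcur)
    dblocks[[i]] <- bb$dp
    gcur <- bb$dx
  }
  be <- linear_bwd(cache$em, params$embed, gcur)
  list(dp = list(embed = be$dp, blocks = dblocks, head = bh$dp))
}

#' Train the conformer peak detector
#'
#' Seeded mini-batch Adam training against the triangular saliency target
#' with mean-squared-error loss.
#'
#' @param windows list with matrices `x` (standardized input windows) and `y`
#'   (triangular targets), as produced by [make_training_windows()].
#' @param config a [peaknet_config()].
#' @param seed integer seed controlling initialization and batch shuffling.
#' @return object of class `peaknet` with elements `params`, `config`,
#'   `history` (per-epoch mean MSE).
#' @export
train_peaknet <- function(windows, config = peaknet_config(), seed = 1L) {
  X <- windows$x; Y <- windows$y
  if (is.null(dim(X)) || nrow(X) < 1L) stop_beat("empty training window set")
  T <- ncol(X); n <- nrow(X)
  with_seed(seed, {
    params <- init_peaknet(config)
    st <- adam_init(params)
    history <- numeric(config$epochs)
    bs <- min(config$batch_size, n)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (s in seq(1L, n, by = bs)) {
        ix <- ord[s:min(s + bs - 1L, n)]
        B <- length(ix)
        xb <- matrix(as.vector(t(X[ix, , drop = FALSE])), ncol = 1L)
        yb <- as.vector(t(Y[ix, , drop = FALSE]))
        fw <- peaknet_fwd(params, xb, config, B, T)
        resid <- as.vector(fw$y) - yb
        losses <- c(losses, mean(resid^2))
        gy <- matrix(2 * resid / length(resid), ncol = 1L)
        bw <- peaknet_bwd(params, fw, config, gy)
        up <- adam_step(params, bw$dp, st, lr = config$lr)
        params <- up$params; st <- up$state
      }
      history[ep] <- mean(losses)
    }
    structure(list(params = params, config = config, history = history),
              class = "peaknet")
  })
}

#' @export
print.peaknet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<peaknet> conformer: %d blocks, dim %d, %d heads, ",
                     "kernel %d, ffn %d; final MSE %.4g\n"),
              cfg$n_blocks, cfg$model_dim, cfg$n_heads, cfg$conv_kernel,
              cfg$ffn_dim, utils::tail(x$history, 1)))
  invisible(x)
}

#' Predict a peak-saliency trace
#'
#' Slides standardized windows (50% overlap) over the waveform and averages
#' the overlapping network outputs into one full-length trace.
#'
#' @param object a trained `peaknet`.
#' @param newdata waveform vector.
#' @param ... unused.
#' @return saliency vector in \[0, 1\] of `length(newdata)`.
#' @export
predict.peaknet <- function(object, newdata, ...) {
  x <- newdata
  T <- object$config$window_len
  if (length(x) < T) stop_beat("signal shorter than the model window")
  hop <- T %/% 2L
  starts <- unique(c(seq(1L, length(x) - T + 1L, by = hop), length(x) - T + 1L))
  acc <- numeric(length(x)); cnt <- numeric(length(x))
  for (s in starts) {
    w <- x[s:(s + T - 1L)]
    sdw <- stats::sd(w)
    w <- (w - mean(w)) / if (sdw > 1e-12) sdw else 1
    fw <- peaknet_fwd(object$params, matrix(w, ncol = 1L), object$config, 1L, T)
    acc[s:(s + T - 1L)] <- acc[s:(s + T - 1L)] + as.vector(fw$y)
    cnt[s:(s + T - 1L)] <- cnt[s:(s + T - 1L)] + 1
  }
  acc / cnt
}

#' Pick peaks from a saliency trace
#'
#' Local maxima with value at or above `threshold`, greedily kept in
#' decreasing value order (ties broken toward the earlier index) subject to a
#' refractory separation.
#'
#' @param saliency numeric trace.
#' @param fs sampling rate of the trace in Hz.
#' @param threshold minimum saliency (default 0.5, the triangular half-height).
#' @param refractory_s minimum peak separation in seconds (default 0.33 s,
#'   about a 180 bpm ceiling).
#' @return sorted 1-based peak indices.
#' @export
pick_peaks <- function(saliency, fs, threshold = 0.5, refractory_s = 0.33) {
  if (refractory_s <= 0) stop_beat("refractory_s must be positive")
  n <- length(saliency)
  if (n < 3L) return(integer(0))
  s <- saliency
  is_max <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n], FALSE)
  if (s[1] > s[2]) is_max[1] <- TRUE
  if (s[n] > s[n - 1]) is_max[n] <- TRUE
  cand <- which(is_max & s >= threshold)
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-s[cand], cand)]
  gap <- max(1L, round(refractory_s * fs))
  taken <- integer(0)
  for (p in ord)
    if (!length(taken) || all(abs(taken - p) >= gap)) taken <- c(taken, p)
  sort(taken)
}

#' Detect R-peaks in a recording
#'
#' Runs the band-passed waveform through the trained conformer and picks
#' peaks from the averaged saliency trace.
#'
#' @param model a trained `peaknet`.
#' @param recording a `doppler_recording` (already band-passed).
#' @param threshold,refractory_s passed to [pick_peaks()].
#' @return 1-based peak indices at the recording's sampling rate.
#' @export
detect_peaks <- function(model, recording, threshold = 0.5, refractory_s = 0.33) {
  sal <- predict(model, recording$samples)
  pick_peaks(sal, recording$fs, threshold, refractory_s)
}
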