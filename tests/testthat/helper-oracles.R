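# Shared oracles and fixture builders. Every expected value asserted in the
# tests is either computed here by an independent route (quadrature, Monte
# Carlo, brute force, hand arithmetic) or frozen from such a computation.

# Max relative error between analytic gradients and central differences on a
# random probe of parameter entries.
grad_check <- function(loss_fn, params, grads, n_probe = 60, eps = 1e-5,
                       probe_seed = 99) {
  pv <- unlist(params, use.names = FALSE)
  gv <- unlist(grads, use.names = FALSE)
  set.seed(probe_seed)
  idx <- sample(length(pv), min(n_probe, length(pv)))
  num <- vapply(idx, function(i) {
    p1 <- pv; p1[i] <- p1[i] + eps
    p2 <- pv; p2[i] <- p2[i] - eps
    (loss_fn(relist(p1, params)) - loss_fn(relist(p2, params))) / (2 * eps)
  }, 0)
  max(abs(num - gv[idx]) / pmax(1e-6, abs(num) + abs(gv[idx])))
}

# Periodogram band energy via the FFT (independent of the package's filters).
band_energy <- function(x, fs, f1, f2) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(p[f >= f1 & f <= f2 & f <= fs / 2])
}

# Peak normalized cross-correlation over all lags.
xcorr_peak <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a))); b <- c(b, numeric(n - length(b)))
  cc <- stats::convolve(a, rev(b), type = "open")
  max(abs(cc)) / sqrt(sum(a^2) * sum(b^2))
}

# Brute-force EER: root of the linearly interpolated FRR - FAR difference,
# located with uniroot at 1e-12 tolerance (independent of compute_eer's
# closed-form segment intersection).
brute_eer <- function(distances, genuine) {
  u <- sort(unique(distances))
  thr <- c(u[1] - 1, u, u[length(u)] + 1)
  g <- distances[genuine]; i <- distances[!genuine]
  frr <- vapply(thr, function(t) mean(g >= t), 0)
  far <- vapply(thr, function(t) mean(i < t), 0)
  dfun <- stats::approxfun(thr, frr - far)
  ffun <- stats::approxfun(thr, frr)
  hit <- which(frr == far)
  if (length(hit)) return(frr[hit[1]])
  root <- stats::uniroot(dfun, range(thr), tol = 1e-12)$root
  ffun(root)
}

# Greedy tolerance matching of detected against true peaks.
match_peaks <- function(detected, truth, tol) {
  used <- logical(length(detected))
  hits <- 0L
  for (p in truth) {
    d <- abs(detected - p)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      hits <- hits + 1L
      used[j] <- TRUE
    }
  }
  list(recall = hits / length(truth),
       false_pos = (length(detected) - hits) / max(1L, length(detected)))
}

# Direct trapezoid quadrature of the Morlet CWT integral for an analytically
# known signal, oversampled in continuous time (sample units).
cwt_quadrature <- function(fun_of_seconds, T, fs, grid, oversample = 16) {
  u <- seq(0, T - 1, by = 1 / oversample)
  xu <- fun_of_seconds(u / fs)
  w <- rep(1, length(u)); w[1] <- w[length(u)] <- 0.5
  O <- matrix(0i, grid$n_freq, T)
  for (s in seq_len(grid$n_freq)) {
    a <- grid$scales[s]
    for (b in 0:(T - 1)) {
      v <- (u - b) / a
      psi <- pi^(-0.25) * exp(-v^2 / 2) * exp(1i * grid$omega0 * v)
      O[s, b + 1] <- sum(xu * Conj(psi) * w) / oversample / sqrt(a)
    }
  }
  O
}

# A segment of length 8 whose peak-to-mean SNR is exactly `s` (for s in
# [1, 8]): max = s, mean of |x| = (s + 7 * (8 - s)/7) / 8 = 1.
segment_with_snr <- function(s) c(s, rep((8 - s) / 7, 7))

# Clean (noise-free) beat recordings for detector tests.
clean_recording <- function(subject_seed, duration = 30, seed = 1) {
  prof <- make_subject_profile(subject_seed, subject_seed * 13 + 1)
  simulate_recording(prof, simulation_config(
    duration = duration, noise_sd = 0, powerline_amp = 0,
    motion_burst_rate = 0, seed = seed))
}

# Small labeled spectrogram set with two clearly distinct synthetic classes
# (different frequency-band blobs) for CVAE sanity runs.
two_class_blobs <- function(n_per_class, size = 16, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_class
  vals <- array(0, c(size, size, n))
  labels <- integer(n)
  for (i in seq_len(n)) {
    lab <- (i - 1L) %% 2L
    rows <- if (lab == 0L) 3:6 else 10:13
    m <- matrix(stats::runif(size * size, 0, 0.15), size, size)
    m[rows, ] <- m[rows, ] + 0.8
    m[, sample(size, 2)] <- m[, sample(size, 2)] + 0.2  # per-item variation
    vals[, , i] <- pmin(m, 1)
    labels[i] <- lab
  }
  list(values = vals, labels = labels)
}
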