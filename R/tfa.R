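## Morlet continuous wavelet transform, beat spectrograms and augmentation.
##
## Each gated beat window is mapped to a time-frequency magnitude image with
## the analytic Morlet wavelet (center angular frequency omega0 = 6). The CWT
## is preferred over the STFT because a log-spaced scale axis resolves both
## the lower and upper ends of the 15-50 Hz cardiac band without committing
## to one fixed window length.

#' Frequency/scale grid for the Morlet CWT
#'
#' Scales follow the Morlet center-frequency relation `a = omega0 * fs /
#' (2 * pi * f)` (scale measured in samples). The default grid spans the
#' cardiac passband with margins, 64 log-spaced frequencies from 10 to 60 Hz
#' at 125 Hz sampling, giving square spectrogram images.
#'
#' @param fs sampling rate in Hz.
#' @param n_freq number of frequency rows.
#' @param fmin,fmax grid limits in Hz (`fmax` must stay below `fs/2`).
#' @param omega0 Morlet center angular frequency.
#' @return object of class `cwt_grid` with descending `frequencies` and
#'   matching `scales`.
#' @export
cwt_grid <- function(fs = 125, n_freq = 64L, fmin = 10, fmax = 60, omega0 = 6) {
  if (fmax >= fs / 2) stop_beat("fmax must be below Nyquist (%g Hz)", fs / 2)
  if (fmin <= 0 || fmin >= fmax) stop_beat("need 0 < fmin < fmax")
  f <- exp(seq(log(fmax), log(fmin), length.out = n_freq))
  structure(list(fs = fs, frequencies = f,
                 scales = omega0 * fs / (2 * pi * f),
                 n_freq = n_freq, omega0 = omega0),
            class = "cwt_grid")
}

# Spectral Morlet filter bank for a (padded) segment length: row s holds
# conj(psi_hat(a_s * omega_k)) over DFT bins; cached per (grid, N).
morlet_bank <- function(grid, N) {
  key <- sprintf("cwt_%s_%d", object_hash(grid[c("frequencies", "omega0")]), N)
  cache_get(key, function() {
    k <- 0:(N - 1)
    omega <- 2 * pi * ifelse(k <= N %/% 2, k, k - N) / N    # rad / sample
    t(vapply(grid$scales, function(a)
      pi^(-0.25) * sqrt(2 * pi) * exp(-(a * omega - grid$omega0)^2 / 2),
      numeric(N)))
  })
}

#' Morlet continuous wavelet transform of a beat segment
#'
#' Computes `W(a, b) = |a|^(-1/2) integral x(t) conj(psi((t - b)/a)) dt` with
#' the Morlet mother wavelet `psi(t) = pi^(-1/4) exp(i omega0 t)
#' exp(-t^2/2)`, time measured in samples. The integral is evaluated in the
#' frequency domain through the wavelet's exact Fourier transform acting on
#' the zero-padded DFT interpolant of the segment — the accurate
#' discretization at the segment's sampling rate, exact for band-limited
#' signals.
#'
#' @param segment numeric vector, length >= 8.
#' @param grid a [cwt_grid()].
#' @return complex matrix, `n_freq` rows (descending frequency) by
#'   `length(segment)` columns.
#' @export
cwt_morlet <- function(segment, grid) {
  T <- length(segment)
  if (T < 8L) stop_beat("segment too short for a CWT")
  if (max(grid$frequencies) >= grid$fs / 2)
    stop_beat("grid contains frequencies above Nyquist")
  N <- 4L * T                              # zero padding against wraparound
  bank <- morlet_bank(grid, N)
  xhat <- stats::fft(c(segment, numeric(N - T)))
  out <- matrix(0i, grid$n_freq, T)
  for (s in seq_len(grid$n_freq)) {
    w <- stats::fft(xhat * bank[s, ], inverse = TRUE) / N
    out[s, ] <- sqrt(grid$scales[s]) * w[seq_len(T)]
  }
  out
}

#' Magnitude spectrogram from CWT coefficients
#'
#' Elementwise magnitude, linearly resampled on the time axis to `n_time`
#' columns, then min-max scaled to \[0, 1\] per spectrogram (an all-constant
#' matrix maps to zeros, guarding the division).
#'
#' @param coefficients complex CWT matrix.
#' @param n_time output time columns (default: number of frequency rows, for
#'   square images).
#' @return numeric matrix in \[0, 1\].
#' @export
to_spectrogram <- function(coefficients, n_time = nrow(coefficients)) {
  m <- Mod(coefficients)
  if (ncol(m) != n_time) m <- resample_time(m, n_time)
  rng <- range(m)
  if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
}

resample_time <- function(m, n_time) {
  old <- seq(0, 1, length.out = ncol(m))
  new <- seq(0, 1, length.out = n_time)
  t(apply(m, 1L, function(r) stats::approx(old, r, xout = new)$y))
}

#' Five-beat moving average of a spectrogram sequence
#'
#' Elementwise mean over a sliding window of five consecutive same-subject
#' spectrograms, each output re-scaled to \[0, 1\]. Averaging suppresses
#' beat-to-beat noise while preserving the subject's stable time-frequency
#' signature.
#'
#' @param spectrograms 3-d array (`n_freq x n_time x n`) or list of matrices,
#'   ordered by time.
#' @return array with `n - 4` slices (zero slices when `n < 5`).
#' @export
moving_average_5 <- function(spectrograms) {
  if (is.list(spectrograms))
    spectrograms <- simplify2array(spectrograms)
  n <- dim(spectrograms)[3]
  if (is.na(n) || n < 5L)
    return(array(0, c(dim(spectrograms)[1:2], 0)))
  out <- array(0, c(dim(spectrograms)[1:2], n - 4L))
  for (i in seq_len(n - 4L)) {
    m <- apply(spectrograms[, , i:(i + 4L), drop = FALSE], c(1, 2), mean)
    rng <- range(m)
    out[, , i] <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  }
  out
}

shift_columns <- function(m, by) {
  # shift the time axis, replicating edge columns
  n <- ncol(m)
  src <- pmin(pmax(seq_len(n) - by, 1L), n)
  m[, src, drop = FALSE]
}

#' Augment a labeled spectrogram set
#'
#' For every input spectrogram emits: two time-shift copies (+-2 columns,
#' edge columns replicated), one time-stretch copy (stretch factor uniform in
#' `stretch_range`, resampled back to the original width), one white-noise
#' copy (additive Gaussian, `noise_sd`, clipped to \[0, 1\]) and mixup pairs
#' drawn within the same subject label (`lambda ~ Beta(0.2, 0.2)`). Mixup is
#' restricted within-class because the conditional prior is label-specific;
#' classes with a single member skip mixup. Deterministic per seed.
#'
#' @param values 3-d array `n_freq x n_time x n`.
#' @param labels integer subject labels, length `n`.
#' @param seed integer seed.
#' @param stretch_range,noise_sd augmentation magnitudes.
#' @param mixup_cross_class allow mixup across labels (off by default).
#' @return list with enlarged `values`, `labels` and logical `augmented`.
#' @export
augment <- function(values, labels, seed = 1L, stretch_range = c(0.9, 1.1),
                    noise_sd = 0.05, mixup_cross_class = FALSE) {
  n <- dim(values)[3]
  if (is.na(n) || n < 1L) stop_beat("empty spectrogram set")
  nt <- dim(values)[2]
  with_seed(seed, {
    out <- list(); lab <- c(); aug <- c()
    emit <- function(m, l, a) {
      out[[length(out) + 1L]] <<- m
      lab <<- c(lab, l); aug <<- c(aug, a)
    }
    for (i in seq_len(n)) {
      m <- values[, , i]
      emit(m, labels[i], FALSE)
      emit(shift_columns(m, 2L), labels[i], TRUE)
      emit(shift_columns(m, -2L), labels[i], TRUE)
      fac <- stats::runif(1, stretch_range[1], stretch_range[2])
      stretched <- resample_time(m, max(4L, round(nt * fac)))
      emit(resample_time(stretched, nt), labels[i], TRUE)
      noisy <- pmin(pmax(m + stats::rnorm(length(m), 0, noise_sd), 0), 1)
      emit(matrix(noisy, nrow(m)), labels[i], TRUE)
    }
    for (i in seq_len(n)) {
      pool <- if (mixup_cross_class) setdiff(seq_len(n), i)
              else setdiff(which(labels == labels[i]), i)
      if (!length(pool)) next
      j <- if (length(pool) == 1L) pool else sample(pool, 1L)
      lambda <- stats::rbeta(1, 0.2, 0.2)
      emit(lambda * values[, , i] + (1 - lambda) * values[, , j],
           labels[i], TRUE)
    }
    list(values = simplify2array(out), labels = lab, augmented = aug)
  })
}
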