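## Band-limiting, decimation, beat segmentation and SNR gating.
##
## Heartbeat-induced chest micro-vibrations occupy roughly 15-50 Hz in the
## Doppler baseband, respiration sits below 10 Hz and power-line interference
## at 60 Hz, so a zero-phase 15-50 Hz band-pass isolates the cardiac
## component. The filtered wave is decimated to 125 Hz, cut into fixed windows
## around each detected peak, and windows are kept only if their peak-to-mean
## ratio (the working SNR definition) clears a split-specific gate: 4 for
## training data, 6 for test data.

#' Band-pass filter specification
#'
#' @param low_cut,high_cut passband edges in Hz.
#' @param order Butterworth prototype order. The default (6) is the lowest
#'   order whose forward-backward (zero-phase) response attenuates 60 Hz by
#'   at least 40 dB at fs = 250 Hz while keeping 30 Hz within 1 dB.
#' @param zero_phase apply the filter forward and backward (no group delay).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 15, high_cut = 50, order = 6L,
                        zero_phase = TRUE) {
  if (!(low_cut > 0 && low_cut < high_cut)) stop_beat("need 0 < low_cut < high_cut")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), zero_phase = zero_phase),
            class = "filter_spec")
}

# Forward-backward IIR filtering with reflection padding, so 60 s records do
# not carry start-up transients into the first beats.
filtfilt_pad <- function(filt, x) {
  np <- min(length(x) - 1L, 3L * (length(filt$a) + length(filt$b)))
  pre <- 2 * x[1] - x[seq(np + 1L, 2L)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - np)]
  y <- c(pre, x, post)
  y <- signal::filter(filt, y)
  y <- rev(signal::filter(filt, rev(y)))
  y[(np + 1L):(np + length(x))]
}

#' Zero-phase band-pass filter a recording
#'
#' @param recording a `doppler_recording` (or numeric vector with `fs` given).
#' @param spec a [filter_spec()].
#' @param fs sampling rate, required when `recording` is a bare vector.
#' @return object of the same kind with filtered samples.
#' @export
bandpass <- function(recording, spec = filter_spec(), fs = NULL) {
  vec <- is.numeric(recording)
  x <- if (vec) recording else recording$samples
  fs <- if (vec) fs else recording$fs
  if (is.null(fs)) stop_beat("sampling rate unknown")
  if (fs <= 2 * spec$high_cut)
    stop_beat("fs = %g Hz cannot represent a %g Hz passband edge", fs, spec$high_cut)
  bf <- signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / (fs / 2),
                       type = "pass")
  y <- if (spec$zero_phase) filtfilt_pad(bf, x) else
    as.numeric(signal::filter(bf, x))
  if (vec) return(y)
  out <- recording
  out$samples <- y
  out
}

#' Decimate a 250 Hz recording to 125 Hz
#'
#' Anti-aliased decimation by 2; peak indices are remapped by halving with
#' round-half-down. Only the 250 -> 125 Hz path of the sensor chain is
#' supported.
#'
#' @param recording a `doppler_recording` at 250 Hz.
#' @return the recording at 125 Hz with remapped `rpeaks`.
#' @export
downsample_to_125 <- function(recording) {
  if (recording$fs != 250) stop_beat("only fs = 250 Hz input is supported")
  x <- recording$samples
  # light anti-alias guard; the 15-50 Hz band is already below the new Nyquist
  lp <- signal::butter(6, 0.8, type = "low")
  y <- filtfilt_pad(lp, x)
  n_out <- floor(length(x) / 2)
  out <- recording
  out$fs <- 125
  out$samples <- y[seq_len(n_out) * 2L - 1L]     # 0-based even samples
  if (!is.null(recording$rpeaks))                # 0-based i -> floor(i/2)
    out$rpeaks <- (recording$rpeaks - 1L) %/% 2L + 1L
  out$beat_only <- NULL
  out
}

#' Cut fixed windows around beat peaks
#'
#' One window per peak, `window_len` samples, with the peak at (1-based)
#' position `window_len/2 + 1`. Peaks too close to either edge are dropped
#' rather than padded, since padding would distort both the SNR and the
#' wavelet transform edges.
#'
#' @param recording `doppler_recording` (typically at 125 Hz).
#' @param peaks 1-based peak sample indices; defaults to `recording$rpeaks`.
#' @param window_len even window length in samples (default 64, i.e. 0.512 s
#'   at 125 Hz — shorter than any plausible beat interval).
#' @return object of class `beat_segments`: a list with `x` (matrix, one row
#'   per surviving segment), `peak` (its center index), `subject_id`.
#' @export
segment_beats <- function(recording, peaks = recording$rpeaks, window_len = 64L) {
  if (window_len %% 2L != 0L) stop_beat("window_len must be even")
  if (is.null(peaks)) peaks <- integer(0)
  half <- window_len %/% 2L
  n <- length(recording$samples)
  keep <- peaks - half >= 1L & peaks + half - 1L <= n
  peaks <- peaks[keep]
  x <- matrix(0, nrow = length(peaks), ncol = window_len)
  for (k in seq_along(peaks))
    x[k, ] <- recording$samples[(peaks[k] - half):(peaks[k] + half - 1L)]
  structure(list(x = x, peak = peaks, subject_id = recording$subject_id,
                 fs = recording$fs, window_len = window_len),
            class = "beat_segments")
}

#' Peak-to-mean segment SNR
#'
#' `max(abs(x)) / mean(abs(x))` — the peak value taken as signal and the
#' average rectified amplitude of the window as noise.
#'
#' @param segment numeric vector (one beat window).
#' @return dimensionless SNR >= 1.
#' @export
segment_snr <- function(segment) {
  if (!length(segment)) stop_beat("empty segment")
  m <- mean(abs(segment))
  if (m == 0) stop_beat("degenerate all-zero segment has undefined SNR")
  max(abs(segment)) / m
}

#' SNR-gate beat segments
#'
#' Training data keep segments with SNR >= 4; test data require SNR >= 6 —
#' the lower training gate deliberately lets noisier beats into training.
#'
#' @param segments a `beat_segments` object (or numeric vector of SNRs).
#' @param split_tag `"train"` or `"test"`.
#' @return the surviving segments (order preserved), with an `snr` field.
#' @export
gate_segments <- function(segments, split_tag) {
  thr <- switch(split_tag, train = 4, test = 6,
                stop_beat("unknown split_tag '%s'", split_tag))
  if (is.numeric(segments)) return(segments[segments >= thr])
  snr <- apply(segments$x, 1L, segment_snr)
  keep <- snr >= thr
  out <- segments
  out$x <- segments$x[keep, , drop = FALSE]
  out$peak <- segments$peak[keep]
  out$snr <- snr[keep]
  out$split_tag <- split_tag
  out
}
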