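rms <- function(x) sqrt(mean(x^2))

test_that("the band-pass chain passes 30 Hz and suppresses 0.3 and 60 Hz", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  gain_db <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- bandpass(x, filter_spec(), fs = fs)
    core <- seq(2 * fs, length(x) - 2 * fs)      # avoid edge transients
    20 * log10(rms(y[core]) / rms(x[core]))
  }
  expect_lt(abs(gain_db(30)), 1)
  expect_lt(gain_db(0.3), -40)
  expect_lt(gain_db(60), -40)
  expect_equal(bandpass(numeric(1000), fs = fs), numeric(1000))
  expect_error(bandpass(numeric(100), filter_spec(), fs = 80), "passband")
})

test_that("filtering is zero-phase for in-band signals", {
  fs <- 250
  set.seed(1)
  # band-limited random input: white noise brickwalled to 20-45 Hz
  n <- 4000
  X <- stats::fft(rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  X[!((f >= 20 & f <= 45) | (f >= fs - 45 & f <= fs - 20))] <- 0
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  y <- bandpass(x, filter_spec(), fs = fs)
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band-passing is idempotent in-band", {
  fs <- 250
  rec <- clean_recording(3, duration = 10)
  y1 <- bandpass(rec$samples, fs = fs)
  y2 <- bandpass(y1, fs = fs)
  core <- seq(2 * fs, length(y1) - 2 * fs)
  expect_lt(abs(20 * log10(rms(y2[core]) / rms(y1[core]))), 1)
})

test_that("decimation to 125 Hz halves lengths and remaps peaks half-down", {
  rec <- beatprint:::new_recording(0, 250, sin(2 * pi * 30 * (0:2499) / 250),
                                   c(11L, 501L, 502L))
  out <- downsample_to_125(rec)
  expect_equal(out$fs, 125)
  expect_length(out$samples, 1250)
  # 0-based peaks 10, 500, 501 -> 5, 250, 250
  expect_identical(out$rpeaks, c(6L, 251L, 251L))
  # 30 Hz amplitude preserved within 1 dB (FFT amplitude oracle)
  amp <- function(x, fs) {
    n <- length(x)
    2 * max(Mod(stats::fft(x))[2:(n %/% 2)]) / n
  }
  expect_lt(abs(20 * log10(amp(out$samples, 125) / amp(rec$samples, 250))), 1)
  expect_error(downsample_to_125(beatprint:::new_recording(0, 125, 1:10)),
               "250")
})

test_that("segmentation is centered, edge-safe and count-preserving", {
  rec <- beatprint:::new_recording(7, 125, rnorm(1000))
  seg <- segment_beats(rec, peaks = c(10L, 100L, 200L, 300L, 400L, 500L, 990L),
                       window_len = 64L)
  expect_equal(nrow(seg$x), 5)                      # 10 and 990 dropped
  expect_identical(seg$peak, c(100L, 200L, 300L, 400L, 500L))
  for (k in seq_along(seg$peak))
    expect_equal(seg$x[k, 33], rec$samples[seg$peak[k]])
  expect_equal(nrow(segment_beats(rec, peaks = integer(0))$x), 0)
  expect_error(segment_beats(rec, peaks = 100L, window_len = 63L), "even")
})

test_that("segment SNR matches hand computations and is scale invariant", {
  expect_equal(segment_snr(rep(3, 10)), 1)
  expect_equal(segment_snr(c(0, 0, 0, 8, 0, 0, 0, 0)), 8)
  x <- rnorm(64)
  expect_equal(segment_snr(3 * x), segment_snr(x))
  expect_equal(segment_snr(-x), segment_snr(x))
  expect_error(segment_snr(numeric(0)), "empty")
  expect_error(segment_snr(numeric(8)), "zero")
})

test_that("SNR gates keep >= 4 for training and >= 6 for test", {
  expect_identical(gate_segments(c(3.9, 4.0, 6.0), "train"), c(4.0, 6.0))
  expect_identical(gate_segments(c(3.9, 4.0, 6.0), "test"), 6.0)
  expect_identical(gate_segments(numeric(0), "train"), numeric(0))
  expect_error(gate_segments(c(1, 2), "validation"), "split_tag")
  # monotonicity: the test-split survivors are a subset of the train survivors
  set.seed(2)
  snrs <- runif(50, 1, 10)
  expect_true(all(gate_segments(snrs, "test") %in% gate_segments(snrs, "train")))
})
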