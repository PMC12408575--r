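test_that("subject profiles are deterministic in the seed and mutually distinct", {
  p1 <- make_subject_profile(0, 1)
  p2 <- make_subject_profile(0, 1)
  expect_identical(p1, p2)

  profs <- list(make_subject_profile(0, 1))
  for (k in 2:4)
    profs[[k]] <- make_subject_profile(k - 1, k * 17, avoid = profs)
  tpls <- lapply(profs, render_beat_template, fs = 250)
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(xcorr_peak(tpls[[i]], tpls[[j]]), 0.95)

  for (p in profs) {
    expect_true(all(p$atoms$freq >= 15 & p$atoms$freq <= 45))
    expect_true(nrow(p$atoms) >= 3 && nrow(p$atoms) <= 6)
    expect_lt(p$respiration_freq, 10)
  }
})

test_that("beat templates have the stated length, normalization and spectrum", {
  atoms <- data.frame(freq = 30, amp = 1, latency = 0, decay = 0.05)
  prof <- subject_profile(0, atoms, mean_rr = 1, rr_sd = 0,
                          respiration_freq = 0.3, respiration_amp = 5)
  tpl <- render_beat_template(prof, 250)
  expect_length(tpl, 125)
  expect_equal(max(abs(tpl)), 1)
  # dominant spectral bin of the single 30 Hz atom (FFT argmax oracle)
  spec <- Mod(stats::fft(c(tpl, numeric(375))))[1:250]
  f <- (0:249) * 250 / 500
  expect_lt(abs(f[which.max(spec)] - 30), 2)

  expect_error(subject_profile(0, atoms[0, ], 1, 0, 0.3, 5), "atom")
  expect_error(subject_profile(0, transform(atoms, freq = 60), 1, 0, 0.3, 5),
               "frequencies")
})

test_that("simulated recordings honor RR statistics, determinism and length", {
  atoms <- data.frame(freq = c(25, 35), amp = c(1, 0.3),
                      latency = c(0, 0.1), decay = c(0.05, 0.03))
  prof <- subject_profile(0, atoms, mean_rr = 1, rr_sd = 0,
                          respiration_freq = 0.25, respiration_amp = 5)
  cfg <- simulation_config(duration = 10, seed = 11)
  rec <- simulate_recording(prof, cfg)
  expect_length(rec$samples, 2500)
  expect_equal(unique(diff(rec$rpeaks)), 250L)       # rr_sd = 0 at 250 Hz
  expect_identical(rec$samples, simulate_recording(prof, cfg)$samples)

  # gaps bounded as [0.5 mean_rr, 2 mean_rr] in samples for a noisy-RR profile
  prof2 <- make_subject_profile(1, 5)
  rec2 <- simulate_recording(prof2, simulation_config(duration = 30, seed = 2))
  gaps <- diff(rec2$rpeaks)
  expect_true(all(gaps >= 0.5 * 250 * prof2$mean_rr))
  expect_true(all(gaps <= 2 * 250 * prof2$mean_rr))

  expect_error(simulate_recording(prof, simulation_config(duration = 0.8)),
               "duration")
})

test_that("respiration dominates below 10 Hz while beats live in 15-50 Hz", {
  prof <- make_subject_profile(2, 9)
  rec <- simulate_recording(prof, simulation_config(
    duration = 20, noise_sd = 0, powerline_amp = 0, motion_burst_rate = 0,
    seed = 3))
  low <- band_energy(rec$samples, 250, 0.05, 10)
  beat_band <- band_energy(rec$samples, 250, 15, 50)
  expect_gt(low, beat_band)                          # respiration dominates raw
})

test_that("after an ideal 15-50 Hz filter the beat train carries >= 90% of energy", {
  for (s in 1:3) {
    prof <- make_subject_profile(s, s * 31)
    rec <- simulate_recording(prof, simulation_config(duration = 30, seed = s))
    # brickwall FFT filter, independent of the package's Butterworth chain
    brick <- function(x) {
      n <- length(x); X <- stats::fft(x)
      f <- (seq_len(n) - 1) * 250 / n
      keep <- (f >= 15 & f <= 50) | (f >= 200 & f <= 235)  # +conjugate band
      X[!keep] <- 0
      Re(stats::fft(X, inverse = TRUE) / n)
    }
    beat_f <- brick(rec$beat_only)
    noise_f <- brick(rec$samples - rec$beat_only)
    expect_gt(sum(beat_f^2) / (sum(beat_f^2) + sum(noise_f^2)), 0.9)
  }
})

test_that("ground-truth peaks sit on local maxima of the beat-only component", {
  prof <- make_subject_profile(4, 77)
  rec <- simulate_recording(prof, simulation_config(duration = 20, seed = 4))
  b <- abs(rec$beat_only)
  for (p in rec$rpeaks) {
    win <- b[max(1, p - 2):min(length(b), p + 2)]
    expect_equal(max(win), max(b[max(1, p - 5):min(length(b), p + 5)]))
  }
})

test_that("recordings round-trip through the CSV + annotation format", {
  rec <- clean_recording(1, duration = 5)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "r.csv")
  write_recording_csv(rec, csv)
  back <- read_recording_csv(csv, fs = 250, subject_id = rec$subject_id,
                             annotation_path = paste0(csv, ".peaks.txt"))
  expect_equal(back$samples, rec$samples)
  expect_identical(back$rpeaks, rec$rpeaks)

  ds <- list(recordings = list(rec))
  manifest <- write_dataset(ds, file.path(dir, "set"), seed = 5)
  again <- read_dataset(manifest)
  expect_equal(again$recordings[[1]]$samples, rec$samples)
  expect_equal(again$seed, 5)
})
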