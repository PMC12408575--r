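test_that("the scale grid follows the Morlet center-frequency relation", {
  g <- cwt_grid(fs = 125, n_freq = 64)
  expect_equal(g$scales, g$omega0 * g$fs / (2 * pi * g$frequencies))
  expect_true(all(diff(g$frequencies) < 0))
  expect_true(all(g$frequencies > 0 & g$frequencies < 125 / 2))
  expect_error(cwt_grid(fs = 125, fmax = 70), "Nyquist")
})

test_that("CWT localizes sinusoids, is linear, and vanishes on zero input", {
  g <- cwt_grid(fs = 125, n_freq = 32)
  t <- (0:63) / 125
  x30 <- sin(2 * pi * 30 * t)
  W <- cwt_morlet(x30, g)
  peak_row <- which.max(rowMeans(Mod(W)))
  expect_lte(abs(peak_row - which.min(abs(g$frequencies - 30))), 1)

  expect_equal(max(Mod(cwt_morlet(numeric(64), g))), 0)
  y <- cos(2 * pi * 20 * t)
  expect_equal(cwt_morlet(x30 + y, g), cwt_morlet(x30, g) + cwt_morlet(y, g),
               tolerance = 1e-10)
  expect_error(cwt_morlet(numeric(4), g), "short")
})

test_that("CWT agrees with direct quadrature of the transform integral", {
  fs <- 125; T <- 64
  taper <- function(t) 0.5 - 0.5 * cos(2 * pi * t / ((T - 1) / fs))
  chirp <- function(t) taper(t) * sin(2 * pi * (15 * t + ((40 - 15) / (2 * (T / fs))) * t^2))
  g <- cwt_grid(fs = fs, n_freq = 16, fmin = 12, fmax = 45)
  W <- cwt_morlet(chirp((0:(T - 1)) / fs), g)
  O <- cwt_quadrature(chirp, T, fs, g, oversample = 8)
  expect_lt(max(abs(W - O)) / max(abs(O)), 0.01)
})

test_that("spectrogram conversion is a bounded, scale-invariant magnitude image", {
  g <- cwt_grid(fs = 125, n_freq = 16)
  set.seed(3)
  x <- rnorm(64)
  sp <- to_spectrogram(cwt_morlet(x, g))
  expect_equal(dim(sp), c(16, 16))
  expect_equal(range(sp), c(0, 1))
  expect_equal(to_spectrogram(cwt_morlet(10 * x, g)), sp)
  expect_equal(to_spectrogram(matrix(5 + 0i, 4, 8), n_time = 8),
               matrix(0, 4, 8))
})

test_that("beat energy concentrates in the template's frequency rows", {
  atoms <- data.frame(freq = c(22, 30), amp = c(1, 0.3),
                      latency = c(0, 0.05), decay = c(0.05, 0.04))
  prof <- subject_profile(0, atoms, 1, 0, 0.3, 5)
  tpl <- render_beat_template(prof, 125)
  g <- cwt_grid(fs = 125, n_freq = 32)
  sp <- to_spectrogram(cwt_morlet(c(tpl, numeric(64 - length(tpl)))[1:64], g))
  rows_near <- which(g$frequencies >= 17 & g$frequencies <= 35)
  expect_gt(sum(sp[rows_near, ]^2) / sum(sp^2), 0.8)  # energy concentration
})

test_that("five-beat moving averages have the stated length and values", {
  set.seed(4)
  one <- matrix(runif(64), 8, 8)
  five_same <- array(rep(one, 5), c(8, 8, 5))
  ma <- moving_average_5(five_same)
  expect_equal(dim(ma)[3], 1)
  rng <- range(one)
  expect_equal(ma[, , 1], (one - rng[1]) / (rng[2] - rng[1]))  # re-normalized

  six <- array(runif(8 * 8 * 6), c(8, 8, 6))
  expect_equal(dim(moving_average_5(six))[3], 2)
  expect_equal(dim(moving_average_5(six[, , 1:4]))[3], 0)

  # alternating all-zero / all-one images: plain mean is 0.4 everywhere,
  # which the guarded re-normalization then maps to zeros
  alt <- array(rep(c(0, 1, 0, 1, 0), each = 64), c(8, 8, 5))
  expect_equal(mean(apply(alt, c(1, 2), mean)), 0.4)
  expect_equal(moving_average_5(alt)[, , 1], matrix(0, 8, 8))
})

test_that("augmentation emits the advertised variants deterministically", {
  set.seed(5)
  vals <- array(runif(8 * 8 * 4), c(8, 8, 4))
  labs <- c(0L, 0L, 1L, 1L)
  a1 <- augment(vals, labs, seed = 9)
  a2 <- augment(vals, labs, seed = 9)
  expect_identical(a1, a2)
  # per input: original + 2 shifts + stretch + noise, plus within-class mixup
  expect_equal(dim(a1$values)[3], 4 * 5 + 4)
  expect_equal(sum(!a1$augmented), 4)
  expect_true(all(a1$values >= 0 & a1$values <= 1))
  # mixup outputs stay within elementwise bounds of their class
  shift <- beatprint:::shift_columns
  m <- vals[, , 1]
  expect_equal(shift(shift(m, 2L), -2L)[, 3:6], m[, 3:6])
  expect_equal(shift(m, 2L)[, 1], m[, 1])        # replicated edge column
  # single-member class: mixup skipped, other variants still emitted
  a3 <- augment(vals[, , 1, drop = FALSE], 0L, seed = 1)
  expect_equal(dim(a3$values)[3], 5)
})

test_that("mixup respects convex-combination bounds within a class", {
  set.seed(6)
  vals <- array(runif(8 * 8 * 6), c(8, 8, 6))
  labs <- rep(0:1, each = 3L)
  a <- augment(vals, labs, seed = 11)
  lo <- apply(vals, c(1, 2), min); hi <- apply(vals, c(1, 2), max)
  for (i in (5 * 6 + 1):dim(a$values)[3]) {      # the mixup block
    expect_true(all(a$values[, , i] >= lo - 1e-12))
    expect_true(all(a$values[, , i] <= hi + 1e-12))
  }
})
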