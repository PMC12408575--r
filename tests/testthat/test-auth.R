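test_that("enrollment computes centers and floored sample variances", {
  gal <- enroll(list(`0` = rbind(c(0, 0), c(2, 0))))
  e <- gal$subjects[["0"]]
  expect_equal(e$center, c(1, 0))
  expect_equal(e$variance, c(2, 1e-6))            # n-1 convention; floor
  expect_equal(e$n_enrolled, 2)

  same <- enroll(list(a = rbind(c(1, 1), c(1, 1), c(1, 1))))
  expect_equal(same$subjects$a$variance, c(1e-6, 1e-6))

  set.seed(1)
  z <- matrix(rnorm(20), 5)
  g1 <- enroll(list(x = z, y = z + 1))
  g2 <- enroll(list(y = z + 1, x = z))
  expect_equal(g1$subjects$x, g2$subjects$x)
  expect_equal(g1$subjects$y, g2$subjects$y)

  expect_error(enroll(list(`0` = rbind(c(1, 2)))), "fewer than 2")
  expect_error(enroll(list(rbind(c(1, 2), c(3, 4)))), "named")
})

test_that("Mahalanobis distance reduces to the hand-computed cases", {
  gal <- enroll(list(s = rbind(c(0, 0), c(0, 0), c(0, 0))))
  gal$subjects$s$variance <- c(9, 1)
  expect_equal(mahalanobis_dist(c(3, 0), gal, "s"), 1)
  expect_equal(mahalanobis_dist(c(0, 0), gal, "s"), 0)
  gal$subjects$s$variance <- c(1, 1)
  expect_equal(mahalanobis_dist(c(3, 4), gal, "s"), 5)   # Euclidean reduction
  # scaling a dimension by c and its variance by c^2 leaves distances fixed
  set.seed(2)
  z <- matrix(rnorm(30), 10)
  gal2 <- enroll(list(a = z))
  d0 <- mahalanobis_dist(c(1, 2, 3), gal2, "a")
  gal3 <- gal2
  gal3$subjects$a$center[2] <- gal3$subjects$a$center[2] * 10
  gal3$subjects$a$variance[2] <- gal3$subjects$a$variance[2] * 100
  expect_equal(mahalanobis_dist(c(1, 2 * 10, 3), gal3, "a"), d0)
})

test_that("verification uses a strict threshold and is monotone in it", {
  gal <- enroll(list(s = rbind(c(0, 0), c(0.1, 0))))
  gal <- set_threshold(gal, "s", 2)
  expect_true(verify_beat(gal$subjects$s$center, "s", gal)$accept)
  d_at <- mahalanobis_dist(c(1, 1), gal, "s")
  gal_eq <- set_threshold(gal, "s", d_at)
  expect_false(verify_beat(c(1, 1), "s", gal_eq)$accept)  # d == thr rejects
  set.seed(3)
  probes <- matrix(rnorm(40), 20)
  accepted <- sapply(seq(0.1, 5, by = 0.1), function(thr) {
    g <- set_threshold(gal, "s", thr)
    sum(apply(probes, 1, function(z) verify_beat(z, "s", g)$accept))
  })
  expect_true(all(diff(accepted) >= 0))
  expect_error(verify_beat(c(0, 0), "ghost", gal), "not enrolled")
})

test_that("five-beat voting accepts on 3-of-5 and agrees with unanimity", {
  gal <- enroll(list(s = rbind(c(0, 0), c(0.1, 0))))
  gal <- set_threshold(gal, "s", 1)
  near <- c(0, 0); far <- c(10, 10)
  out <- verify_voted(rbind(near, near, near, far, far), "s", gal)
  expect_true(out$accept); expect_equal(out$votes_for, 3)
  out2 <- verify_voted(rbind(near, near, far, far, far), "s", gal)
  expect_false(out2$accept)
  out3 <- verify_voted(rbind(near, near, near, near, near), "s", gal)
  expect_true(out3$accept); expect_equal(out3$votes_for, 5)
  expect_error(verify_voted(rbind(near, near), "s", gal), "exactly 5")
})

test_that("identification picks the nearest center with deterministic ties", {
  centers <- list(`1` = c(0, 0), `3` = c(4, 0), `4` = c(0, 4))
  gal <- enroll(lapply(centers, function(c0) rbind(c0, c0, c0)))
  for (id in names(centers))
    expect_equal(identify_beat(centers[[id]], gal), id)
  expect_equal(identify_beat(c(2, 0), gal), "1")   # equidistant 1 vs 3
  solo <- enroll(list(`9` = rbind(c(1, 1), c(1, 2))))
  expect_equal(identify_beat(c(100, 100), solo), "9")
})

test_that("voted identification takes the mode, then the closer tied subject", {
  centers <- list(`1` = c(0, 0), `4` = c(10, 0), `9` = c(0, 10))
  gal <- enroll(lapply(centers, function(c0) rbind(c0, c0, c0)))
  z <- rbind(c(0, 0), c(0.1, 0), c(0.2, 0), c(10, 0), c(10, 0.1))
  expect_equal(identify_voted(z, gal), "1")        # mode 3 vs 2
  # 2-2-1 tie between ids 1 and 4; id 1 has the smaller mean distance
  z2 <- rbind(c(0, 0), c(0.1, 0), c(9, 0), c(12, 0), c(0, 10))
  expect_equal(identify_voted(z2, gal), "1")
  z3 <- matrix(rep(c(10, 0), 5), 5, byrow = TRUE)
  expect_equal(identify_voted(z3, gal), "4")
  expect_error(identify_voted(z[1:3, ], gal), "exactly 5")
})

test_that("galleries are invariant to enrollment order", {
  set.seed(4)
  zs <- lapply(1:3, function(i) matrix(rnorm(12) + i, 4))
  names(zs) <- as.character(1:3)
  g1 <- enroll(zs)
  g2 <- enroll(zs[c(3, 1, 2)])
  probe <- rnorm(3)
  expect_equal(identify_beat(probe, g1), identify_beat(probe, g2))
  for (id in names(zs))
    expect_equal(mahalanobis_dist(probe, g1, id), mahalanobis_dist(probe, g2, id))
})
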