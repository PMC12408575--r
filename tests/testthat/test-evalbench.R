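test_that("the 48/12 s split partitions samples and annotations half-open", {
  rec <- beatprint:::new_recording(0, 250, rnorm(15000),
                                   c(100L, 11999L, 12000L, 12001L, 14000L))
  sp <- split_train_test(rec, 48, 12)
  expect_length(sp$train$samples, 12000)
  expect_length(sp$test$samples, 3000)
  # 0-based peak 12000 (1-based 12001) sits exactly on the 48 s boundary -> test
  expect_identical(sp$train$rpeaks, c(100L, 11999L, 12000L))
  expect_identical(sp$test$rpeaks, c(1L, 2000L))
  short <- beatprint:::new_recording(0, 250, rnorm(12000))
  expect_error(split_train_test(short, 48, 12), "too short")
})

test_that("LOOCV tasks balance impostors at 1/(K-2) and exclude the held-out subject", {
  # 13 subjects with 22 train items each: each contributes floor(22/11) = 2
  set.seed(5)
  feats <- lapply(1:13, function(i) list(
    train = array(runif(4 * 4 * 22), c(4, 4, 22)),
    test = array(runif(4 * 4 * 3), c(4, 4, 3))))
  names(feats) <- as.character(0:12)
  feats[["0"]]$train[] <- 99                       # held-out marker value
  task <- build_loocv_task(feats, held_out = "0", target = "1", seed = 3)
  expect_equal(sum(task$labels == 0L), 11 * 2)
  expect_equal(sum(task$labels == 1L), 22)
  # the held-out subject's (marked) items never appear in training
  expect_false(any(task$values == 99))
  # impostor probes include the held-out subject
  expect_true("0" %in% names(task$impostors))
  expect_false("1" %in% names(task$impostors))
  expect_identical(task$values,
                   build_loocv_task(feats, "0", "1", seed = 3)$values)
  expect_error(build_loocv_task(feats, "0", "0", seed = 1), "differ")
  expect_error(build_loocv_task(feats, "99", "1", seed = 1), "missing")
})

test_that("FRR/FAR sweeps have the stated limits and monotonicity", {
  cv <- sweep_frr_far(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  # below-minimum sentinel: reject everything; above-maximum: accept everything
  expect_equal(cv$frr[1], 1); expect_equal(cv$far[1], 0)
  expect_equal(cv$frr[length(cv$frr)], 0)
  expect_equal(cv$far[length(cv$far)], 1)
  # hand count at threshold 3: genuine {1,2} accepted, impostors {3,4} rejected
  k <- which(cv$thresholds == 3)
  expect_equal(cv$frr[k], 0); expect_equal(cv$far[k], 0)
  expect_true(all(diff(cv$frr) <= 0))
  expect_true(all(diff(cv$far) >= 0))
  expect_error(sweep_frr_far(c(1, 2), c(TRUE, TRUE)), "impostor")
})

test_that("interpolated EER matches the brute-force oracle on random instances", {
  expect_equal(compute_eer(sweep_frr_far(c(1, 2, 3, 4),
                                         c(TRUE, TRUE, FALSE, FALSE)))$eer, 0)
  expect_equal(compute_eer(sweep_frr_far(rep(c(1, 2), 2),
                                         c(TRUE, TRUE, FALSE, FALSE)))$eer, 0.5)
  set.seed(6)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    d <- round(runif(n, 0, 10), sample(c(1, 2), 1))
    g <- runif(n) < 0.5
    if (!any(g)) g[1] <- TRUE
    if (all(g)) g[n] <- FALSE
    cv <- sweep_frr_far(d, g)
    expect_true(all(diff(cv$frr) <= 0) && all(diff(cv$far) >= 0))
    expect_lt(abs(compute_eer(cv)$eer - brute_eer(d, g)), 1e-9)
  }
})

test_that("verification and identification metrics match hand arithmetic", {
  acc <- c(rep(TRUE, 9), FALSE, rep(FALSE, 8), TRUE, TRUE)
  gen <- c(rep(TRUE, 10), rep(FALSE, 10))
  vm <- verification_metrics(acc, gen)
  expect_equal(vm$bac, 0.85)                       # (0.9 + 0.8) / 2
  expect_equal(vm$f1, 2 * 9 / (2 * 9 + 2 + 1))
  expect_equal(c(vm$tp, vm$fn, vm$tn, vm$fp), c(9, 1, 8, 2))
  perfect <- verification_metrics(gen, gen)
  expect_equal(perfect$bac, 1); expect_equal(perfect$f1, 1)
  all_acc <- verification_metrics(rep(TRUE, 20), gen)
  expect_equal(all_acc$bac, 0.5)
  expect_error(verification_metrics(acc[1:10], gen[1:10]), "genuine")

  im <- identification_metrics(c("a", "a", "b", "b"), c("a", "a", "a", "b"))
  expect_equal(im$acc, 0.75)
  expect_equal(im$macro_acc, mean(c(2 / 3, 1)))
  im2 <- identification_metrics(rep("a", 4), c("a", "a", "b", "b"))
  expect_equal(im2$macro_acc, 0.5)
  im3 <- identification_metrics(c("x", "y", "q"), c("x", "z", "q"))
  expect_equal(unname(im3$per_subject[c("x", "z", "q")]), c(1, 0, 1))
  expect_equal(im3$macro_acc, mean(c(1, 0, 1)))
  expect_error(identification_metrics("a", c("a", "b")), "mismatch")
})

test_that("voted trial scores reduce majority voting to a median threshold", {
  d <- c(0.1, 0.2, 5, 6, 7, 1, 1, 1, 9, 9)
  vs <- beatprint:::voted_scores(d)
  expect_equal(vs, c(5, 1))                        # medians of the two groups
  # median < tau  <=>  at least 3 of 5 distances < tau
  for (tau in c(0.5, 2, 5.5, 8)) {
    for (gi in 1:2) {
      grp <- d[((gi - 1) * 5 + 1):(gi * 5)]
      expect_equal(vs[gi] < tau, sum(grp < tau) >= 3)
    }
  }
})
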