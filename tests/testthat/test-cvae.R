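test_that("closed-form KL matches hand-computed cases and stays non-negative", {
  expect_equal(kl_gaussians(c(0, 1), c(0, 0), c(0, 1), c(0, 0)), 0)
  expect_equal(kl_gaussians(1, 0, 0, 0), 0.5)        # unit variances, dim 1
  # scaling both distributions' sd by c leaves KL of matched means unchanged
  expect_equal(kl_gaussians(2, log(4), 0, log(4)),
               kl_gaussians(1, 0, 0, 0))
  set.seed(10)
  for (i in 1:20) {
    d <- sample(1:5, 1)
    expect_gte(kl_gaussians(rnorm(d), runif(d, -1, 1),
                            rnorm(d), runif(d, -1, 1)), 0)
  }
  expect_error(kl_gaussians(1, Inf, 0, 0), "finite")
})

test_that("reparameterized samples have the requested moments and seeding", {
  z0 <- reparameterize(rep(2, 4), rep(-50, 4), seed = 1)
  expect_equal(as.vector(z0), rep(2, 4), tolerance = 1e-9)
  n <- 1e5
  z <- reparameterize(matrix(0, n, 1), matrix(0, n, 1), seed = 2)
  expect_lt(abs(mean(z)), 3 / sqrt(n))
  expect_lt(abs(var(as.vector(z)) - 1), 3 * sqrt(2 / n))
  expect_identical(reparameterize(1:3, c(0, 0, 0), seed = 5),
                   reparameterize(1:3, c(0, 0, 0), seed = 5))
})

test_that("encoder and decoder respect shapes, bounds and determinism", {
  cfg <- cvae_config(latent_dim = 4L, n_labels = 2L, input_shape = c(16L, 16L),
                     channels = c(2L, 4L), batch_size = 4L, epochs = 1L)
  set.seed(3)
  m <- structure(list(params = beatprint:::init_cvae(cfg), config = cfg),
                 class = "cvae")
  vals <- array(runif(16 * 16 * 5), c(16, 16, 5))
  en <- cvae_encode(m, vals)
  expect_equal(dim(en$mean), c(5, 4))
  expect_equal(dim(en$log_variance), c(5, 4))
  expect_identical(en, cvae_encode(m, vals))
  expect_equal(en$mean[2, ], cvae_encode(m, vals[, , 2])$mean[1, ])
  de <- cvae_decode(m, en$mean)
  expect_equal(dim(de), c(16, 16, 5))
  expect_true(all(de >= 0 & de <= 1))
  expect_error(cvae_encode(m, array(0, c(8, 8, 2))), "shape")
  expect_error(cvae_decode(m, matrix(0, 2, 7)), "columns")
  pr <- cvae_prior(m, c(0L, 1L))
  expect_equal(dim(pr$mean), c(2, 4))
  expect_true(all(is.finite(pr$log_variance)))
})

test_that("the loss decomposes additively and rejects bad labels", {
  cfg <- cvae_config(latent_dim = 3L, n_labels = 2L, input_shape = c(8L, 8L),
                     channels = c(2L,  3L), batch_size = 4L, epochs = 1L)
  set.seed(4)
  m <- structure(list(params = beatprint:::init_cvae(cfg), config = cfg),
                 class = "cvae")
  vals <- array(runif(8 * 8 * 6), c(8, 8, 6))
  l <- cvae_loss(m, vals, rep(0:1, 3), seed = 1)
  expect_equal(l$total, l$recon + l$kl)
  expect_gte(l$kl, 0)
  expect_error(cvae_loss(m, vals, rep(2L, 6), seed = 1), "range")
})

test_that("training separates two synthetic classes in latent space", {
  data <- two_class_blobs(30, size = 16, seed = 8)
  cfg <- cvae_config(latent_dim = 6L, n_labels = 2L, input_shape = c(16L, 16L),
                     channels = c(3L, 6L), batch_size = 20L, epochs = 50L,
                     lr = 2e-3)
  m <- train_cvae(data$values, data$labels, cfg, seed = 5)
  expect_lt(tail(m$history$total, 1), 0.5 * m$history$total[1])
  expect_true(all(is.finite(unlist(m$history))))
  m2 <- train_cvae(data$values, data$labels, cfg, seed = 5)
  expect_identical(m$history, m2$history)

  en <- cvae_encode(m, data$values)
  c0 <- colMeans(en$mean[data$labels == 0, ])
  c1 <- colMeans(en$mean[data$labels == 1, ])
  spread <- mean(c(apply(en$mean[data$labels == 0, ], 1, function(z) sqrt(sum((z - c0)^2))),
                   apply(en$mean[data$labels == 1, ], 1, function(z) sqrt(sum((z - c1)^2)))))
  expect_gt(sqrt(sum((c0 - c1)^2)), spread)

  # the label-conditioned priors reproduce >= 90% of training labels
  pr <- cvae_prior(m, 0:1)
  assign_prior <- apply(en$mean, 1, function(z)
    which.min(c(sum((z - pr$mean[1, ])^2), sum((z - pr$mean[2, ])^2))) - 1L)
  expect_gte(mean(assign_prior == data$labels), 0.9)

  # reconstruction beats the mean-image baseline on training items
  rec <- predict(m, data$values, type = "reconstruction")
  mean_img <- apply(data$values, c(1, 2), mean)
  mse_model <- mean((rec - data$values)^2)
  mse_base <- mean(sweep(data$values, c(1, 2), mean_img)^2)
  expect_lt(mse_model, 0.5 * mse_base)

  expect_error(train_cvae(data$values, rep(0L, length(data$labels)), cfg, 1),
               "absent")
})
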