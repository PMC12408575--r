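## Conditional variational autoencoder with a label-conditioned Gaussian
## prior.
##
## The encoder q(z | x) maps a beat spectrogram to a diagonal Gaussian in
## latent space WITHOUT seeing the subject label; the prior p(z | y) is a
## small network mapping the one-hot subject label to a Gaussian; the decoder
## reconstructs the spectrogram from a reparameterized latent sample. The
## training loss is reconstruction MSE (summed over pixels, the decoder mean
## being sigmoid-bounded in [0, 1]) plus the closed-form KL divergence
## between posterior and label prior, averaged over the batch. Minimizing the
## KL term pulls each subject's posteriors toward that subject's prior,
## organizing the latent space into per-subject clusters that the
## authentication stage exploits.

#' CVAE configuration
#'
#' Published training settings by default: latent dimension 50, batch size
#' 64, 300 epochs, Adam with learning rate 1e-5.
#'
#' @param latent_dim latent space dimension.
#' @param n_labels number of subject labels (>= 2).
#' @param input_shape `c(n_freq, n_time)` of the spectrograms; each side must
#'   be divisible by `2^length(channels)`.
#' @param channels convolution channels per encoder block (mirrored in the
#'   decoder); each block is conv 3x3 -> ReLU -> 2x2 max pool.
#' @param prior_hidden hidden width of the label-to-prior network.
#' @param batch_size,epochs,lr training hyperparameters.
#' @return object of class `cvae_config`.
#' @export
cvae_config <- function(latent_dim = 50L, n_labels = 2L,
                        input_shape = c(64L, 64L), channels = c(16L, 32L, 64L),
                        prior_hidden = 64L, batch_size = 64L, epochs = 300L,
                        lr = 1e-5) {
  if (latent_dim < 1L) stop_beat("latent_dim must be positive")
  if (n_labels < 2L) stop_beat("need at least two labels")
  if (any(input_shape %% 2L^length(channels) != 0L))
    stop_beat("input_shape must be divisible by 2^length(channels)")
  structure(as.list(environment()), class = "cvae_config")
}

init_conv3 <- function(cin, cout) {
  list(W = init_mat(cout, 9L * cin, sqrt(2 / (9 * cin))), b = numeric(cout))
}

init_cvae <- function(cfg) {
  ch <- c(1L, cfg$channels)
  nb <- length(cfg$channels)
  hf <- cfg$input_shape[1] %/% 2L^nb
  wf <- cfg$input_shape[2] %/% 2L^nb
  flat <- hf * wf * cfg$channels[nb]
  dec_ch <- c(rev(cfg$channels), 1L)
  list(enc = list(convs = lapply(seq_len(nb), function(i) init_conv3(ch[i], ch[i + 1])),
                  fc = init_linear(flat, 2L * cfg$latent_dim, sqrt(1 / flat) * 0.5)),
       dec = list(fc = init_linear(cfg$latent_dim, flat),
                  convs = lapply(seq_len(nb), function(i)
                    init_conv3(dec_ch[i], dec_ch[i + 1]))),
       prior = list(l1 = init_linear(cfg$n_labels, cfg$prior_hidden),
                    l2 = init_linear(cfg$prior_hidden, 2L * cfg$latent_dim, 0.05)))
}

# stack an (F x T x B) spectrogram array into a (1 x B*F*T) channels-first
# pixel matrix, pixels row-major within each image
stack_images <- function(values) {
  B <- dim(values)[3]
  matrix(unlist(lapply(seq_len(B), function(b) as.vector(t(values[, , b])))),
         nrow = 1L)
}
unstack_images <- function(x, H, W, B) {
  out <- array(0, c(H, W, B))
  for (b in seq_len(B))
    out[, , b] <- t(matrix(x[1L, ((b - 1L) * H * W + 1L):(b * H * W)], W, H))
  out
}

LV_CLAMP <- 8

enc_fwd <- function(p, x, cfg, B) {
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]
  caches <- list()
  h <- x
  for (i in seq_along(p$convs)) {
    cv <- conv3x3c_fwd(h, p$convs[[i]], B, H, W)
    rl <- relu_fwd(cv$y)
    mp <- maxpool2c_fwd(rl$y, B, H, W)
    caches[[i]] <- list(cv = cv, rl = rl, mp = mp)
    h <- mp$y; H <- H %/% 2L; W <- W %/% 2L
  }
  flat <- flatten_mapsc(h, B)
  fc <- linear_fwd(flat, p$fc)
  L <- cfg$latent_dim
  raw_lv <- fc$y[, L + seq_len(L), drop = FALSE]
  list(mean = fc$y[, seq_len(L), drop = FALSE],
       log_variance = pmin(pmax(raw_lv, -LV_CLAMP), LV_CLAMP),
       lv_mask = abs(raw_lv) < LV_CLAMP,
       caches = caches, fc = fc, B = B, C_last = nrow(h))
}

enc_bwd <- function(p, cache, cfg, dmean, dlv) {
  dlv <- dlv * cache$lv_mask
  bfc <- linear_bwd(cache$fc, p$fc, cbind(dmean, dlv))
  g <- unflatten_mapsc(bfc$dx, cache$B, cache$C_last)
  dconvs <- vector("list", length(p$convs))
  for (i in rev(seq_along(p$convs))) {
    g <- maxpool2c_bwd(cache$caches[[i]]$mp, g)
    g <- relu_bwd(cache$caches[[i]]$rl, g)
    bcv <- conv3x3c_bwd(cache$caches[[i]]$cv, p$convs[[i]], g)
    dconvs[[i]] <- bcv$dp
    g <- bcv$dx
  }
  list(dp = list(convs = dconvs, fc = bfc$dp))
}

dec_fwd <- function(p, z, cfg, B) {
  nb <- length(p$convs)
  hf <- cfg$input_shape[1] %/% 2L^nb; wf <- cfg$input_shape[2] %/% 2L^nb
  fc <- linear_fwd(z, p$fc)
  rl0 <- relu_fwd(fc$y)
  h <- unflatten_mapsc(rl0$y, B, cfg$channels[nb])
  H <- hf; W <- wf
  caches <- list()
  for (i in seq_len(nb)) {
    up <- upsample2c_fwd(h, B, H, W)
    H <- 2L * H; W <- 2L * W
    cv <- conv3x3c_fwd(up$y, p$convs[[i]], B, H, W)
    if (i < nb) { act <- relu_fwd(cv$y); h <- act$y }
    else { act <- sigmoid_fwd(cv$y); h <- act$y }
    caches[[i]] <- list(up = up, cv = cv, act = act)
  }
  list(y = h, fc = fc, rl0 = rl0, caches = caches, B = B,
       C0 = cfg$channels[nb])
}

dec_bwd <- function(p, cache, cfg, g) {
  nb <- length(p$convs)
  dconvs <- vector("list", nb)
  for (i in rev(seq_len(nb))) {
    cc <- cache$caches[[i]]
    g <- if (i < nb) relu_bwd(cc$act, g) else sigmoid_bwd(cc$act, g)
    bcv <- conv3x3c_bwd(cc$cv, p$convs[[i]], g)
    dconvs[[i]] <- bcv$dp
    g <- upsample2c_bwd(cc$up, bcv$dx)
  }
  g0 <- relu_bwd(cache$rl0, flatten_mapsc(g, cache$B))
  bfc <- linear_bwd(cache$fc, p$fc, g0)
  list(dz = bfc$dx, dp = list(fc = bfc$dp, convs = dconvs))
}

prior_fwd <- function(p, onehot, L) {
  c1 <- linear_fwd(onehot, p$l1)
  rl <- relu_fwd(c1$y)
  c2 <- linear_fwd(rl$y, p$l2)
  raw_lv <- c2$y[, L + seq_len(L), drop = FALSE]
  list(mean = c2$y[, seq_len(L), drop = FALSE],
       log_variance = pmin(pmax(raw_lv, -LV_CLAMP), LV_CLAMP),
       lv_mask = abs(raw_lv) < LV_CLAMP, c1 = c1, rl = rl, c2 = c2)
}
prior_bwd <- function(p, cache, dmean, dlv) {
  dlv <- dlv * cache$lv_mask
  b2 <- linear_bwd(cache$c2, p$l2, cbind(dmean, dlv))
  gr <- relu_bwd(cache$rl, b2$dx)
  b1 <- linear_bwd(cache$c1, p$l1, gr)
  list(dp = list(l1 = b1$dp, l2 = b2$dp))
}

#' Closed-form KL divergence between diagonal Gaussians
#'
#' `KL(q || p)` per row, with `q = N(mu_q, exp(logvar_q))` and
#' `p = N(mu_p, exp(logvar_p))`:
#' `sum_d [ (logvar_p - logvar_q)/2 + (var_q + (mu_q - mu_p)^2)/(2 var_p) - 1/2 ]`.
#'
#' @param mu_q,logvar_q posterior mean and log-variance (vectors or matrices,
#'   one row per item).
#' @param mu_p,logvar_p prior mean and log-variance of matching shape.
#' @return numeric vector, one non-negative value per item.
#' @export
kl_gaussians <- function(mu_q, logvar_q, mu_p, logvar_p) {
  if (is.null(dim(mu_q))) {
    mu_q <- rbind(mu_q); logvar_q <- rbind(logvar_q)
    mu_p <- rbind(mu_p); logvar_p <- rbind(logvar_p)
  }
  if (!all(is.finite(logvar_q)) || !all(is.finite(logvar_p)))
    stop_beat("non-finite log-variance")
  term <- 0.5 * (logvar_p - logvar_q) +
    (exp(logvar_q) + (mu_q - mu_p)^2) / (2 * exp(logvar_p)) - 0.5
  unname(rowSums(term))
}

#' Reparameterized Gaussian sample
#'
#' `z = mu + eps * exp(logvar / 2)` with `eps ~ N(0, I)`; the standard
#' reparameterization trick, seeded for determinism.
#'
#' @param mean,log_variance matrices (items x dims) or vectors.
#' @param seed integer seed.
#' @return sample of the same shape as `mean`.
#' @export
reparameterize <- function(mean, log_variance, seed = 1L) {
  with_seed(seed, mean + stats::rnorm(length(mean)) * exp(0.5 * log_variance))
}

one_hot <- function(labels, K) {
  oh <- matrix(0, length(labels), K)
  oh[cbind(seq_along(labels), labels + 1L)] <- 1
  oh
}

# One forward/backward pass over a batch. Returns loss components and, when
# `want_grads`, parameter gradients for Adam.
cvae_batch <- function(params, values, labels, cfg, eps, want_grads = TRUE) {
  B <- dim(values)[3]
  L <- cfg$latent_dim
  x <- stack_images(values)
  en <- enc_fwd(params$enc, x, cfg, B)
  z <- en$mean + eps * exp(0.5 * en$log_variance)
  de <- dec_fwd(params$dec, z, cfg, B)
  oh <- one_hot(labels, cfg$n_labels)
  pr <- prior_fwd(params$prior, oh, L)
  resid <- de$y - x
  hw <- ncol(x) / B
  recon_i <- colSums(matrix(resid^2, nrow = hw))          # sum over pixels
  kl_i <- kl_gaussians(en$mean, en$log_variance, pr$mean, pr$log_variance)
  out <- list(total = mean(recon_i + kl_i), recon = mean(recon_i),
              kl = mean(kl_i))
  if (!want_grads) return(out)
  dxhat <- 2 * resid / B
  db <- dec_bwd(params$dec, de, cfg, dxhat)
  dmu <- (en$mean - pr$mean) / exp(pr$log_variance) / B
  dmu_q <- db$dz + dmu
  dlv_q <- db$dz * 0.5 * eps * exp(0.5 * en$log_variance) +
    (-0.5 + 0.5 * exp(en$log_variance - pr$log_variance)) / B
  dmu_p <- -dmu
  dlv_p <- (0.5 - (exp(en$log_variance) + (en$mean - pr$mean)^2) /
              (2 * exp(pr$log_variance))) / B
  eb <- enc_bwd(params$enc, en, cfg, dmu_q, dlv_q)
  pb <- prior_bwd(params$prior, pr, dmu_p, dlv_p)
  out$grads <- list(enc = eb$dp, dec = db$dp, prior = pb$dp)
  out
}

#' CVAE loss on a batch
#'
#' Mean over the batch of pixel-summed reconstruction MSE plus the KL
#' divergence between the encoder posterior and the label-conditioned prior.
#'
#' @param model a trained or freshly initialized `cvae` (see [train_cvae()]).
#' @param values spectrogram array `n_freq x n_time x n`.
#' @param labels 0-based integer labels in `[0, n_labels)`.
#' @param seed seed for the reparameterization noise.
#' @return list with `total`, `recon`, `kl` (`total == recon + kl`).
#' @export
cvae_loss <- function(model, values, labels, seed = 1L) {
  if (any(labels < 0L | labels >= model$config$n_labels))
    stop_beat("label out of range [0, %d)", model$config$n_labels)
  eps <- with_seed(seed, matrix(stats::rnorm(dim(values)[3] * model$config$latent_dim),
                                dim(values)[3], model$config$latent_dim))
  out <- cvae_batch(model$params, values, labels, model$config, eps,
                    want_grads = FALSE)
  out[c("total", "recon", "kl")]
}

#' Train the conditional VAE
#'
#' Seeded shuffled mini-batch Adam training. Every label in
#' `[0, n_labels)` must be present in `labels`.
#'
#' @param values spectrogram array `n_freq x n_time x n`, entries in \[0, 1\].
#' @param labels 0-based integer subject labels.
#' @param config a [cvae_config()].
#' @param seed integer seed (initialization, shuffling, reparameterization).
#' @return object of class `cvae` with `params`, `config` and `history`
#'   (per-epoch data.frame: total, recon, kl).
#' @export
train_cvae <- function(values, labels, config, seed = 1L) {
  n <- dim(values)[3]
  if (is.na(n) || n < 1L) stop_beat("empty training set")
  missing_lab <- setdiff(0:(config$n_labels - 1L), unique(labels))
  if (length(missing_lab))
    stop_beat("label class(es) %s absent from training data",
              paste(missing_lab, collapse = ", "))
  with_seed(seed, {
    params <- init_cvae(config)
    st <- adam_init(params)
    hist <- matrix(0, config$epochs, 3L,
                   dimnames = list(NULL, c("total", "recon", "kl")))
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      acc <- c(0, 0, 0); nb <- 0L
      for (s in seq(1L, n, by = config$batch_size)) {
        ix <- ord[s:min(s + config$batch_size - 1L, n)]
        eps <- matrix(stats::rnorm(length(ix) * config$latent_dim),
                      length(ix), config$latent_dim)
        r <- cvae_batch(params, values[, , ix, drop = FALSE], labels[ix],
                        config, eps)
        if (!all(is.finite(unlist(r[c("total", "recon", "kl")]))))
          stop_beat("non-finite loss at epoch %d", ep)
        up <- adam_step(params, r$grads, st, lr = config$lr)
        params <- up$params; st <- up$state
        acc <- acc + c(r$total, r$recon, r$kl); nb <- nb + 1L
      }
      hist[ep, ] <- acc / nb
    }
    structure(list(params = params, config = config,
                   history = as.data.frame(hist)),
              class = "cvae")
  })
}

#' @export
print.cvae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<cvae> latent %d, %d labels, input %dx%d, channels %s; ",
                     "final loss %.4g (recon %.4g, kl %.4g)\n"),
              cfg$latent_dim, cfg$n_labels, cfg$input_shape[1], cfg$input_shape[2],
              paste(cfg$channels, collapse = "/"),
              utils::tail(x$history$total, 1), utils::tail(x$history$recon, 1),
              utils::tail(x$history$kl, 1)))
  invisible(x)
}

#' Encode spectrograms to latent Gaussians
#'
#' Deterministic given the trained weights; the subject label is not an
#' input — the encoder must discover identity structure on its own.
#'
#' @param model a `cvae`.
#' @param values array `n_freq x n_time x n` (a single matrix is promoted).
#' @return list with matrices `mean` and `log_variance` (`n x latent_dim`).
#' @export
cvae_encode <- function(model, values) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!all(dim(values)[1:2] == model$config$input_shape))
    stop_beat("input shape %s does not match model input %s",
              paste(dim(values)[1:2], collapse = "x"),
              paste(model$config$input_shape, collapse = "x"))
  en <- enc_fwd(model$params$enc, stack_images(values), model$config,
                dim(values)[3])
  list(mean = en$mean, log_variance = en$log_variance)
}

#' Decode latent points to spectrograms
#'
#' @param model a `cvae`.
#' @param z latent matrix (`n x latent_dim`) or single vector.
#' @return array `n_freq x n_time x n` with values in \[0, 1\].
#' @export
cvae_decode <- function(model, z) {
  if (is.null(dim(z))) z <- rbind(z)
  if (ncol(z) != model$config$latent_dim)
    stop_beat("z must have %d columns", model$config$latent_dim)
  de <- dec_fwd(model$params$dec, z, model$config, nrow(z))
  unstack_images(de$y, model$config$input_shape[1],
                 model$config$input_shape[2], nrow(z))
}

#' Label-conditioned prior parameters
#'
#' @param model a `cvae`.
#' @param labels 0-based integer labels.
#' @return list with matrices `mean` and `log_variance`.
#' @export
cvae_prior <- function(model, labels) {
  pr <- prior_fwd(model$params$prior, one_hot(labels, model$config$n_labels),
                  model$config$latent_dim)
  list(mean = pr$mean, log_variance = pr$log_variance)
}

#' @export
predict.cvae <- function(object, newdata, type = c("latent", "reconstruction"),
                         ...) {
  type <- match.arg(type)
  en <- cvae_encode(object, newdata)
  if (type == "latent") return(en)
  cvae_decode(object, en$mean)
}
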