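## Minimal neural-network core: dense, layer-norm, attention, depthwise 1-D
## convolution, 3x3 2-D convolution (as nine shifted GEMMs), 2x2 max pooling,
## zero-stuffed upsampling (transposed convolution when followed by a 3x3
## convolution) and Adam. Forward passes return a cache consumed by the
## matching backward pass; gradients are derived by hand and verified against
## numerical differentiation in the test suite.
##
## Data layout conventions:
##  * sequence batches: rows are positions, stacked sequence-after-sequence
##    ((B*T) x d), with (B, T) carried alongside;
##  * image batches: rows are pixels in row-major order within an image,
##    images stacked ((B*H*W) x C).

rowbc <- function(x, w) x * rep(w, each = nrow(x))   # broadcast vector over rows

## ---- dense -----------------------------------------------------------------

linear_fwd <- function(x, p) list(y = x %*% p$W + rep(p$b, each = nrow(x)), x = x)
linear_bwd <- function(cache, p, g) {
  list(dx = g %*% t(p$W),
       dp = list(W = crossprod(cache$x, g), b = colSums(g)))
}

## ---- activations -----------------------------------------------------------

relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_bwd <- function(cache, g) g * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))
sigmoid_fwd <- function(x) { s <- sigmoid(x); list(y = s, s = s) }
sigmoid_bwd <- function(cache, g) g * cache$s * (1 - cache$s)

swish_fwd <- function(x) { s <- sigmoid(x); list(y = x * s, x = x, s = s) }
swish_bwd <- function(cache, g) g * (cache$s + cache$x * cache$s * (1 - cache$s))

## ---- layer norm (over feature columns, per row) ----------------------------

layernorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = rowbc(xhat, p$g) + rep(p$b, each = nrow(x)), xhat = xhat, inv = inv)
}
layernorm_bwd <- function(cache, p, g) {
  dxhat <- rowbc(g, p$g)
  xhat <- cache$xhat
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dp = list(g = colSums(g * xhat), b = colSums(g)))
}

## ---- softmax (per row) -----------------------------------------------------

softmax_rows <- function(x) {
  e <- exp(x - x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))])
  e / rowSums(e)
}

## ---- multi-head self-attention (one sequence, T x d) -----------------------

mhsa_fwd <- function(x, p, n_heads) {
  d <- ncol(x); dk <- d %/% n_heads
  q <- x %*% p$Wq + rep(p$bq, each = nrow(x))
  k <- x %*% p$Wk + rep(p$bk, each = nrow(x))
  v <- x %*% p$Wv + rep(p$bv, each = nrow(x))
  o <- matrix(0, nrow(x), d)
  A <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    ix <- ((h - 1L) * dk + 1L):(h * dk)
    s <- tcrossprod(q[, ix, drop = FALSE], k[, ix, drop = FALSE]) / sqrt(dk)
    A[[h]] <- softmax_rows(s)
    o[, ix] <- A[[h]] %*% v[, ix, drop = FALSE]
  }
  y <- o %*% p$Wo + rep(p$bo, each = nrow(x))
  list(y = y, x = x, q = q, k = k, v = v, o = o, A = A,
       n_heads = n_heads, dk = dk)
}

mhsa_bwd <- function(cache, p, g) {
  x <- cache$x; dk <- cache$dk
  dWo <- crossprod(cache$o, g); dbo <- colSums(g)
  do <- g %*% t(p$Wo)
  dq <- matrix(0, nrow(x), ncol(x)); dk_ <- dq; dv <- dq
  for (h in seq_len(cache$n_heads)) {
    ix <- ((h - 1L) * dk + 1L):(h * dk)
    A <- cache$A[[h]]
    dA <- tcrossprod(do[, ix, drop = FALSE], cache$v[, ix, drop = FALSE])
    dv[, ix] <- crossprod(A, do[, ix, drop = FALSE])
    ds <- A * (dA - rowSums(dA * A))          # softmax Jacobian per row
    dq[, ix] <- ds %*% cache$k[, ix, drop = FALSE] / sqrt(dk)
    dk_[, ix] <- crossprod(ds, cache$q[, ix, drop = FALSE]) / sqrt(dk)
  }
  dx <- dq %*% t(p$Wq) + dk_ %*% t(p$Wk) + dv %*% t(p$Wv)
  list(dx = dx,
       dp = list(Wq = crossprod(x, dq), bq = colSums(dq),
                 Wk = crossprod(x, dk_), bk = colSums(dk_),
                 Wv = crossprod(x, dv), bv = colSums(dv),
                 Wo = dWo, bo = dbo))
}

## ---- shift-index caches ----------------------------------------------------

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (is.null(.idx_cache[[key]])) .idx_cache[[key]] <- build()
  .idx_cache[[key]]
}

# Row indices that shift every sequence in a stacked (B*T) batch by `s`
# positions; positions off the sequence point at the guard row B*T + 1.
seq_shift_idx <- function(B, T, s) {
  key <- sprintf("seq_%d_%d_%d", B, T, s)
  cache_get(key, function() {
    p <- seq_len(T) + s
    bad <- p < 1L | p > T
    idx <- rep((seq_len(B) - 1L) * T, each = T) + rep(p, times = B)
    idx[rep(bad, times = B)] <- B * T + 1L
    idx
  })
}

# Out-of-range source positions index an all-zero guard row appended to the
# input, so gathers need no per-call NA handling.
pad_input <- function(x) rbind(x, numeric(ncol(x)))

## ---- 3x3 im2col patch matrix ----------------------------------------------

# Column-block j of the result holds the input shifted by the j-th kernel
# offset; one GEMM against the (9*Cin x Cout) weight matrix then computes the
# convolution for every output pixel.
im2col3x3 <- function(x, B, H, W) {
  n <- nrow(x); C <- ncol(x)
  xp <- pad_input(x)
  out <- matrix(0, n, 9L * C)
  j <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    j <- j + 1L
    out[, ((j - 1L) * C + 1L):(j * C)] <-
      xp[img_shift_idx(B, H, W, dr, dc), , drop = FALSE]
  }
  out
}

## ---- depthwise 1-D convolution (same padding) ------------------------------

dwconv1d_fwd <- function(x, p, B, T) {
  k <- nrow(p$W); half <- (k - 1L) %/% 2L
  xp <- pad_input(x)
  y <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(k)) {
    xs <- xp[seq_shift_idx(B, T, j - half - 1L), , drop = FALSE]
    y <- y + rowbc(xs, p$W[j, ])
  }
  list(y = y + rep(p$b, each = nrow(x)), xp = xp, B = B, T = T, k = k,
       half = half)
}
dwconv1d_bwd <- function(cache, p, g) {
  k <- cache$k; half <- cache$half
  gp <- pad_input(g)
  dW <- matrix(0, k, ncol(g)); dx <- matrix(0, nrow(g), ncol(g))
  for (j in seq_len(k)) {
    s <- j - half - 1L
    xs <- cache$xp[seq_shift_idx(cache$B, cache$T, s), , drop = FALSE]
    dW[j, ] <- colSums(xs * g)
    dx <- dx + rowbc(gp[seq_shift_idx(cache$B, cache$T, -s), , drop = FALSE],
                     p$W[j, ])
  }
  list(dx = dx, dp = list(W = dW, b = colSums(g)))
}

## ---- 3x3 2-D convolution, same padding, as 9 shifted GEMMs -----------------

# Row indices for shifting every image in a stacked (B*H*W) pixel batch by
# (dr, dc); zero-padded border positions point at the guard row B*H*W + 1.
img_shift_idx <- function(B, H, W, dr, dc) {
  key <- sprintf("img_%d_%d_%d_%d_%d", B, H, W, dr, dc)
  cache_get(key, function() {
    r <- rep(seq_len(H), each = W) + dr
    c <- rep(seq_len(W), times = H) + dc
    p <- (r - 1L) * W + c
    bad <- r < 1L | r > H | c < 1L | c > W
    idx <- rep((seq_len(B) - 1L) * H * W, each = H * W) + rep(p, times = B)
    idx[rep(bad, times = B)] <- B * H * W + 1L
    idx
  })
}

# p$W is a (9*Cin x Cout) matrix, row blocks ordered by kernel offset
# (dr, dc) in row-major order, channels within a block.
conv3x3_fwd <- function(x, p, B, H, W) {
  cols <- im2col3x3(x, B, H, W)
  list(y = cols %*% p$W + rep(p$b, each = nrow(x)),
       cols = cols, C_in = ncol(x), B = B, H = H, W = W)
}
conv3x3_bwd <- function(cache, p, g) {
  B <- cache$B; H <- cache$H; W <- cache$W; C <- cache$C_in
  gs <- rbind(g %*% t(p$W), 0)            # (n+1) x 9*Cin, guard row appended
  dx <- matrix(0, nrow(g), C)
  j <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    j <- j + 1L
    dx <- dx + gs[img_shift_idx(B, H, W, -dr, -dc),
                  ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  list(dx = dx, dp = list(W = crossprod(cache$cols, g), b = colSums(g)))
}

## ---- channels-first 2-D ops ------------------------------------------------
##
## The image ops used by the spectrogram autoencoder store feature maps as
## (C x B*H*W) matrices: pixel gathers are then column subsets, which R
## performs as contiguous column copies (much faster than row gathers).

pad_cols <- function(x) cbind(x, 0)

im2col3x3c <- function(x, B, H, W) {
  C <- nrow(x)
  xp <- pad_cols(x)
  out <- matrix(0, 9L * C, ncol(x))
  j <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    j <- j + 1L
    out[((j - 1L) * C + 1L):(j * C), ] <-
      xp[, img_shift_idx(B, H, W, dr, dc), drop = FALSE]
  }
  out
}

# p$W is (Cout x 9*Cin); p$b length Cout
conv3x3c_fwd <- function(x, p, B, H, W) {
  cols <- im2col3x3c(x, B, H, W)
  list(y = p$W %*% cols + p$b, cols = cols, C_in = nrow(x),
       B = B, H = H, W = W)
}
conv3x3c_bwd <- function(cache, p, g) {
  B <- cache$B; H <- cache$H; W <- cache$W; C <- cache$C_in
  gs <- pad_cols(crossprod(p$W, g))       # 9*Cin x (n+1)
  dx <- matrix(0, C, ncol(g))
  j <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    j <- j + 1L
    dx <- dx + gs[((j - 1L) * C + 1L):(j * C),
                  img_shift_idx(B, H, W, -dr, -dc), drop = FALSE]
  }
  list(dx = dx, dp = list(W = tcrossprod(g, cache$cols), b = rowSums(g)))
}

maxpool2c_fwd <- function(x, B, H, W) {
  g <- list(x[, pool_idx(B, H, W, 0L, 0L), drop = FALSE],
            x[, pool_idx(B, H, W, 0L, 1L), drop = FALSE],
            x[, pool_idx(B, H, W, 1L, 0L), drop = FALSE],
            x[, pool_idx(B, H, W, 1L, 1L), drop = FALSE])
  y <- pmax(g[[1]], g[[2]], g[[3]], g[[4]])
  arg <- 1L * (g[[1]] == y)
  arg[g[[2]] == y & arg == 0L] <- 2L
  arg[g[[3]] == y & arg == 0L] <- 3L
  arg[g[[4]] == y & arg == 0L] <- 4L
  list(y = y, arg = arg, B = B, H = H, W = W, n_in = ncol(x))
}
maxpool2c_bwd <- function(cache, g) {
  B <- cache$B; H <- cache$H; W <- cache$W
  dx <- matrix(0, nrow(g), cache$n_in)
  off <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  for (j in 1:4) {
    idx <- pool_idx(B, H, W, off[[j]][1], off[[j]][2])
    dx[, idx] <- dx[, idx] + g * (cache$arg == j)
  }
  dx
}

upsample2c_fwd <- function(x, B, H, W) {
  list(y = pad_cols(x)[, upsample_idx(B, H, W), drop = FALSE],
       B = B, H = H, W = W)
}
upsample2c_bwd <- function(cache, g) {
  g[, downsample_idx(cache$B, cache$H, cache$W), drop = FALSE]
}

# (C x B*H*W) maps <-> (B x H*W*C) flat rows for the dense heads
flatten_mapsc <- function(x, B) {
  hw <- ncol(x) %/% B
  out <- matrix(0, B, hw * nrow(x))
  for (b in seq_len(B))
    out[b, ] <- as.vector(x[, ((b - 1L) * hw + 1L):(b * hw)])
  out
}
unflatten_mapsc <- function(f, B, C) {
  hw <- ncol(f) %/% C
  out <- matrix(0, C, B * hw)
  for (b in seq_len(B))
    out[, ((b - 1L) * hw + 1L):(b * hw)] <- matrix(f[b, ], C, hw)
  out
}

## ---- 2x2 max pooling (stride 2) --------------------------------------------

pool_idx <- function(B, H, W, r0, c0) {
  key <- sprintf("pool_%d_%d_%d_%d_%d", B, H, W, r0, c0)
  cache_get(key, function() {
    Ho <- H %/% 2L; Wo <- W %/% 2L
    r <- rep(seq_len(Ho) * 2L - 1L + r0, each = Wo)
    c <- rep(seq_len(Wo) * 2L - 1L + c0, times = Ho)
    p <- (r - 1L) * W + c
    rep((seq_len(B) - 1L) * H * W, each = Ho * Wo) + rep(p, times = B)
  })
}

maxpool2_fwd <- function(x, B, H, W) {
  g <- list(x[pool_idx(B, H, W, 0L, 0L), , drop = FALSE],
            x[pool_idx(B, H, W, 0L, 1L), , drop = FALSE],
            x[pool_idx(B, H, W, 1L, 0L), , drop = FALSE],
            x[pool_idx(B, H, W, 1L, 1L), , drop = FALSE])
  y <- pmax(g[[1]], g[[2]], g[[3]], g[[4]])
  arg <- 1L * (g[[1]] == y)
  arg[g[[2]] == y & arg == 0L] <- 2L
  arg[g[[3]] == y & arg == 0L] <- 3L
  arg[g[[4]] == y & arg == 0L] <- 4L
  list(y = y, arg = arg, B = B, H = H, W = W, n_in = nrow(x))
}
maxpool2_bwd <- function(cache, g) {
  B <- cache$B; H <- cache$H; W <- cache$W
  dx <- matrix(0, cache$n_in, ncol(g))
  off <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  for (j in 1:4) {
    idx <- pool_idx(B, H, W, off[[j]][1], off[[j]][2])
    dx[idx, ] <- dx[idx, ] + g * (cache$arg == j)
  }
  dx
}

## ---- zero-stuffed 2x upsampling --------------------------------------------

upsample_idx <- function(B, H, W) {
  key <- sprintf("up_%d_%d_%d", B, H, W)
  cache_get(key, function() {
    Ho <- 2L * H; Wo <- 2L * W
    r <- rep(seq_len(Ho), each = Wo); c <- rep(seq_len(Wo), times = Ho)
    odd <- r %% 2L == 1L & c %% 2L == 1L
    p <- ((r + 1L) %/% 2L - 1L) * W + (c + 1L) %/% 2L
    idx <- rep((seq_len(B) - 1L) * H * W, each = Ho * Wo) + rep(p, times = B)
    idx[!rep(odd, times = B)] <- B * H * W + 1L    # guard row
    idx
  })
}

# inverse map: output row holding input pixel (b, i, j) of the 2x upsampling
downsample_idx <- function(B, H, W) {
  key <- sprintf("down_%d_%d_%d", B, H, W)
  cache_get(key, function() {
    r <- rep(seq_len(H), each = W); c <- rep(seq_len(W), times = H)
    p <- (2L * r - 2L) * 2L * W + 2L * c - 1L
    rep((seq_len(B) - 1L) * 4L * H * W, each = H * W) + rep(p, times = B)
  })
}

upsample2_fwd <- function(x, B, H, W) {
  list(y = pad_input(x)[upsample_idx(B, H, W), , drop = FALSE],
       B = B, H = H, W = W)
}
upsample2_bwd <- function(cache, g) {
  g[downsample_idx(cache$B, cache$H, cache$W), , drop = FALSE]
}

## ---- image <-> flat reshaping ----------------------------------------------

flatten_maps <- function(x, B) {
  hw <- nrow(x) %/% B
  out <- matrix(0, B, hw * ncol(x))
  for (b in seq_len(B)) out[b, ] <- as.vector(x[((b - 1L) * hw + 1L):(b * hw), ])
  out
}
unflatten_maps <- function(f, B, C) {
  hw <- ncol(f) %/% C
  out <- matrix(0, B * hw, C)
  for (b in seq_len(B)) out[((b - 1L) * hw + 1L):(b * hw), ] <- matrix(f[b, ], hw, C)
  out
}

## ---- parameter initialization and Adam -------------------------------------

init_mat <- function(nr, nc, scale = sqrt(2 / nr)) matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
init_linear <- function(d_in, d_out, scale = sqrt(1 / d_in))
  list(W = init_mat(d_in, d_out, scale), b = numeric(d_out))
init_layernorm <- function(d) list(g = rep(1, d), b = numeric(d))

map_leaves <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]]))
    return(stats::setNames(lapply(seq_along(args[[1]]), function(i)
      do.call(map_leaves, c(list(f), lapply(args, `[[`, i)))), names(args[[1]])))
  do.call(f, args)
}

adam_init <- function(params)
  list(m = map_leaves(function(p) p * 0, params),
       v = map_leaves(function(p) p * 0, params), t = 0L)

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_leaves(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- map_leaves(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  params <- map_leaves(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                       params, state$m, state$v)
  list(params = params, state = state)
}

zero_like <- function(params) map_leaves(function(p) p * 0, params)
add_grads <- function(a, b) map_leaves(`+`, a, b)
scale_grads <- function(a, s) map_leaves(function(p) p * s, a)
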