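# Internal neural-network machinery for the convolutional VAE.
#
# Batches are stored sample-major: a batch of B sequences of length L
# with C channels is a (B*L) x C matrix, rows (b-1)*L + 1 ... b*L
# holding sample b. Convolutions are computed by gathering kernel taps
# into an im2col matrix and multiplying by a (k*Cin) x Cout weight
# matrix, so all heavy lifting is BLAS.

# Gather maps for a strided 1-D convolution. Out-of-range (padding) taps
# point at a per-sample zero row appended below the input, which keeps
# the row indices within one tap position duplicate-free so that indexed
# accumulation works in the backward pass.
make_conv_map <- function(B, L, k, stride, pad) {
  Lout <- as.integer(floor((L + 2 * pad - k) / stride) + 1)
  base <- rep((seq_len(B) - 1L) * L, each = Lout)
  zrow <- L * B + rep(seq_len(B), each = Lout)
  idx <- vector("list", k)
  for (j in seq_len(k)) {
    rid <- (seq_len(Lout) - 1L) * stride + j - pad
    valid <- rid >= 1L & rid <= L
    g <- base + rep(rid, B)
    g[!rep(valid, B)] <- zrow[!rep(valid, B)]
    idx[[j]] <- g
  }
  list(idx = idx, B = B, L = L, Lout = Lout, k = k)
}

conv_fwd <- function(X, W, b, map) {
  C <- ncol(X)
  X0 <- rbind(X, matrix(0, map$B, C))
  cols <- do.call(cbind, lapply(map$idx, function(ii) X0[ii, , drop = FALSE]))
  Y <- cols %*% W
  Y <- sweep(Y, 2, b, "+")
  list(Y = Y, cols = cols)
}

conv_bwd <- function(dY, W, map, cols, C_in) {
  dW <- crossprod(cols, dY)
  db <- colSums(dY)
  dcols <- dY %*% t(W)
  dX0 <- matrix(0, map$B * map$L + map$B, C_in)
  for (j in seq_len(map$k)) {
    block <- dcols[, ((j - 1) * C_in + 1):(j * C_in), drop = FALSE]
    ii <- map$idx[[j]]
    dX0[ii, ] <- dX0[ii, ] + block
  }
  list(dX = dX0[seq_len(map$B * map$L), , drop = FALSE], dW = dW, db = db)
}

# Transposed convolution with stride 2 as zero-stuffing (length L -> 2L)
# followed by a stride-1 convolution with padding 1.
make_stuff_idx <- function(B, L) {
  rep((seq_len(B) - 1L) * 2L * L, each = L) + (2L * seq_len(L) - 1L)
}

tconv_fwd <- function(X, W, b, map2, stuff_idx) {
  C <- ncol(X)
  Xs <- matrix(0, map2$B * map2$L, C)
  Xs[stuff_idx, ] <- X
  out <- conv_fwd(Xs, W, b, map2)
  out
}

tconv_bwd <- function(dY, W, map2, cols, C_in, stuff_idx) {
  g <- conv_bwd(dY, W, map2, cols, C_in)
  g$dX <- g$dX[stuff_idx, , drop = FALSE]
  g
}

# (B*L) x C  <->  B x (L*C), feature index t + (c-1)*L
flatten_seq <- function(X, B, L, C) {
  matrix(aperm(array(X, c(L, B, C)), c(2, 1, 3)), B)
}
unflatten_seq <- function(F_, B, L, C) {
  matrix(aperm(array(F_, c(B, L, C)), c(2, 1, 3)), B * L)
}

glorot <- function(n_in, n_out, nrow_, ncol_) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(nrow_ * ncol_, -lim, lim), nrow_, ncol_)
}

# Parameter initialization for the mirrored 3-block architecture.
init_vae_params <- function(config) {
  f <- config$filters; k <- config$kernel_size; D <- config$latent_dim
  C0 <- config$input_shape[2]
  L3 <- config$input_shape[1] / 8
  flat <- L3 * f[3]
  list(
    e1_W = glorot(k * C0, f[1], k * C0, f[1]),    e1_b = numeric(f[1]),
    e2_W = glorot(k * f[1], f[2], k * f[1], f[2]), e2_b = numeric(f[2]),
    e3_W = glorot(k * f[2], f[3], k * f[2], f[3]), e3_b = numeric(f[3]),
    mu_W = glorot(flat, D, flat, D),               mu_b = numeric(D),
    lv_W = glorot(flat, D, flat, D),               lv_b = numeric(D),
    d0_W = glorot(D, flat, D, flat),               d0_b = numeric(flat),
    t1_W = glorot(k * f[3], f[2], k * f[3], f[2]), t1_b = numeric(f[2]),
    t2_W = glorot(k * f[2], f[1], k * f[2], f[1]), t2_b = numeric(f[1]),
    t3_W = glorot(k * f[1], C0, k * f[1], C0),     t3_b = numeric(C0))
}

# Per-batch-size cache of gather maps.
vae_maps <- function(model, B) {
  key <- as.character(B)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  L <- model$config$input_shape[1]
  k <- model$config$kernel_size
  maps <- list(
    c1 = make_conv_map(B, L, k, 2L, 1L),
    c2 = make_conv_map(B, L / 2, k, 2L, 1L),
    c3 = make_conv_map(B, L / 4, k, 2L, 1L),
    u1 = make_conv_map(B, L / 4, k, 1L, 1L),
    u2 = make_conv_map(B, L / 2, k, 1L, 1L),
    u3 = make_conv_map(B, L, k, 1L, 1L),
    s1 = make_stuff_idx(B, L / 8),
    s2 = make_stuff_idx(B, L / 4),
    s3 = make_stuff_idx(B, L / 2))
  model$cache[[key]] <- maps
  maps
}

# Full forward pass. X is (B*512) x 6; eps is B x D (0 for deterministic
# inference). Returns all intermediates needed for the backward pass.
vae_fwd <- function(model, X, B, eps) {
  p <- model$params
  cfg <- model$config
  L <- cfg$input_shape[1]; f <- cfg$filters; D <- cfg$latent_dim
  mp <- vae_maps(model, B)
  c1 <- conv_fwd(X, p$e1_W, p$e1_b, mp$c1);  h1 <- tanh(c1$Y)
  c2 <- conv_fwd(h1, p$e2_W, p$e2_b, mp$c2); h2 <- tanh(c2$Y)
  c3 <- conv_fwd(h2, p$e3_W, p$e3_b, mp$c3); h3 <- tanh(c3$Y)
  fl <- flatten_seq(h3, B, L / 8, f[3])
  mu <- sweep(fl %*% p$mu_W, 2, p$mu_b, "+")
  lv <- sweep(fl %*% p$lv_W, 2, p$lv_b, "+")
  lv <- pmin(pmax(lv, -15), 15)
  z <- mu + exp(lv / 2) * eps
  g0 <- sweep(z %*% p$d0_W, 2, p$d0_b, "+"); hg <- tanh(g0)
  u3 <- unflatten_seq(hg, B, L / 8, f[3])
  t1 <- tconv_fwd(u3, p$t1_W, p$t1_b, mp$u1, mp$s1); d1 <- tanh(t1$Y)
  t2 <- tconv_fwd(d1, p$t2_W, p$t2_b, mp$u2, mp$s2); d2 <- tanh(t2$Y)
  t3 <- tconv_fwd(d2, p$t3_W, p$t3_b, mp$u3, mp$s3); xhat <- tanh(t3$Y)
  list(c1 = c1, h1 = h1, c2 = c2, h2 = h2, c3 = c3, h3 = h3, fl = fl,
       mu = mu, lv = lv, z = z, g0 = g0, hg = hg, u3 = u3,
       t1 = t1, d1 = d1, t2 = t2, d2 = d2, t3 = t3, xhat = xhat,
       maps = mp, B = B)
}

# Loss on a forward pass (reporting scale; see vae_loss for contracts).
vae_fwd_loss <- function(fw, X, kl_weight) {
  mse <- mean((X - fw$xhat)^2)
  kl <- mean(rowSums(0.5 * (exp(fw$lv) + fw$mu^2 - 1 - fw$lv)))
  list(mse = mse, kl = kl, total = mse + kl_weight * kl)
}

# Backward pass of total = mse + kl_weight * kl.
vae_bwd <- function(model, fw, X, eps, kl_weight) {
  p <- model$params
  cfg <- model$config
  L <- cfg$input_shape[1]; f <- cfg$filters
  B <- fw$B
  mp <- fw$maps
  n_el <- B * L * cfg$input_shape[2]
  g <- list()
  dxhat <- 2 * (fw$xhat - X) / n_el
  dt3 <- dxhat * (1 - fw$xhat^2)
  b3 <- tconv_bwd(dt3, p$t3_W, mp$u3, fw$t3$cols, f[1], mp$s3)
  g$t3_W <- b3$dW; g$t3_b <- b3$db
  dd2 <- b3$dX * (1 - fw$d2^2)
  b2 <- tconv_bwd(dd2, p$t2_W, mp$u2, fw$t2$cols, f[2], mp$s2)
  g$t2_W <- b2$dW; g$t2_b <- b2$db
  dd1 <- b2$dX * (1 - fw$d1^2)
  b1 <- tconv_bwd(dd1, p$t1_W, mp$u1, fw$t1$cols, f[3], mp$s1)
  g$t1_W <- b1$dW; g$t1_b <- b1$db
  dhg <- flatten_seq(b1$dX, B, L / 8, f[3])
  dg0 <- dhg * (1 - fw$hg^2)
  g$d0_W <- crossprod(fw$z, dg0); g$d0_b <- colSums(dg0)
  dz <- dg0 %*% t(p$d0_W)
  # KL gradients (mean over batch of the per-sample sum over dims)
  dmu <- dz + kl_weight * fw$mu / B
  dlv <- dz * eps * exp(fw$lv / 2) / 2 +
    kl_weight * (exp(fw$lv) - 1) / (2 * B)
  clamped <- fw$lv <= -15 | fw$lv >= 15
  dlv[clamped] <- 0
  g$mu_W <- crossprod(fw$fl, dmu); g$mu_b <- colSums(dmu)
  g$lv_W <- crossprod(fw$fl, dlv); g$lv_b <- colSums(dlv)
  dfl <- dmu %*% t(p$mu_W) + dlv %*% t(p$lv_W)
  dh3 <- unflatten_seq(dfl, B, L / 8, f[3])
  dc3 <- dh3 * (1 - fw$h3^2)
  e3 <- conv_bwd(dc3, p$e3_W, mp$c3, fw$c3$cols, f[2])
  g$e3_W <- e3$dW; g$e3_b <- e3$db
  dc2 <- e3$dX * (1 - fw$h2^2)
  e2 <- conv_bwd(dc2, p$e2_W, mp$c2, fw$c2$cols, f[1])
  g$e2_W <- e2$dW; g$e2_b <- e2$db
  dc1 <- e2$dX * (1 - fw$h1^2)
  e1 <- conv_bwd(dc1, p$e1_W, mp$c1, fw$c1$cols, cfg$input_shape[2])
  g$e1_W <- e1$dW; g$e1_b <- e1$db
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
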