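#' VAE configuration
#'
#' Architecture and training hyper-parameters of the convolutional
#' variational autoencoder. The encoder has three convolutional blocks
#' (kernel 3, stride 2, tanh) whose filter counts default to 32/64/128,
#' giving intermediate temporal lengths 256/128/64 for the 512-sample
#' input; the decoder mirrors them with transposed convolutions. The
#' latent layer holds `latent_dim` (default 12) Gaussian features.
#'
#' `kl_weight` balances the reconstruction and regularization terms of
#' `total = mse + kl_weight * kl`. Its default, `1/(512*6)`, makes the
#' optimized objective identical to the classic evidence lower bound
#' with the squared reconstruction error summed over all 3072 matrix
#' elements; reported `mse` stays on the per-element scale and `kl` in
#' nats per epoch.
#'
#' @param input_shape epoch shape, samples x channels.
#' @param filters three encoder filter counts (decoder mirrors).
#' @param kernel_size convolution kernel size.
#' @param latent_dim number of latent features.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param early_stop_patience epochs without test-loss improvement
#'   before stopping (best weights restored).
#' @param min_delta minimum improvement counted by early stopping.
#' @param kl_weight KL weight in the total loss.
#' @param seed integer seed for weight init, shuffling and sampling.
#' @return List of class `vae_config`.
#' @export
vae_config <- function(input_shape = c(512, 6), filters = c(32, 64, 128),
                       kernel_size = 3, latent_dim = 12,
                       learning_rate = 0.001, batch_size = 64,
                       max_epochs = 200, early_stop_patience = 10,
                       min_delta = 1e-5, kl_weight = 1 / prod(input_shape),
                       seed = 1) {
  stopifnot(length(input_shape) == 2, input_shape[1] %% 8 == 0,
            length(filters) == 3, all(filters >= 1),
            kernel_size %% 2 == 1, latent_dim >= 1, learning_rate > 0,
            batch_size >= 1, max_epochs >= 1, kl_weight >= 0)
  structure(list(
    input_shape = as.integer(input_shape), filters = as.integer(filters),
    kernel_size = as.integer(kernel_size), latent_dim = as.integer(latent_dim),
    encoder_layer_nodes = as.integer(input_shape[1] / c(2, 4, 8)),
    activation = "tanh",
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    early_stop_patience = as.integer(early_stop_patience),
    min_delta = min_delta, kl_weight = kl_weight, seed = as.integer(seed)),
    class = "vae_config")
}

#' Build an untrained VAE
#'
#' Initializes all weights (Glorot-uniform) deterministically from
#' `config$seed`.
#'
#' @param config a [vae_config()].
#' @return List of class `vae_model` with `config`, `params`, `trained`.
#' @export
build_vae <- function(config = vae_config()) {
  stopifnot(inherits(config, "vae_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  structure(list(config = config, params = init_vae_params(config),
                 cache = new.env(parent = emptyenv()), trained = FALSE,
                 report = NULL),
            class = "vae_model")
}

#' @export
print.vae_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<vae_model> %dx%d -> %d latent features; filters %s; %s\n",
              cfg$input_shape[1], cfg$input_shape[2], cfg$latent_dim,
              paste(cfg$filters, collapse = "/"),
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

# Accept a single 512x6 matrix, a gait_epoch, a list of either, or an
# n x 512 x 6 array; return the stacked (n*512) x 6 matrix plus n.
epochs_to_matrix <- function(x, input_shape = c(512, 6)) {
  L <- input_shape[1]; C <- input_shape[2]
  if (inherits(x, "gait_epoch")) x <- list(x)
  if (is.matrix(x)) x <- list(x)
  if (is.array(x) && length(dim(x)) == 3) {
    n <- dim(x)[1]
    stopifnot(dim(x)[2] == L, dim(x)[3] == C)
    out <- matrix(aperm(x, c(2, 1, 3)), n * L, C)
    return(list(X = out, n = n))
  }
  stopifnot(is.list(x), length(x) >= 1)
  mats <- lapply(x, function(e) {
    m <- if (inherits(e, "gait_epoch")) e$data else as.matrix(e)
    stopifnot(nrow(m) == L, ncol(m) == C)
    m
  })
  list(X = do.call(rbind, mats), n = length(mats))
}

#' VAE loss decomposition
#'
#' `mse` is the mean squared error over all matrix elements; `kl` is the
#' Kullback-Leibler divergence of the diagonal-Gaussian posterior from
#' the standard normal prior, summed over latent dimensions and averaged
#' over the batch (nats); `total = mse + kl_weight * kl` exactly.
#'
#' @param x,x_hat input and reconstruction, (B*512) x 6 or single epoch
#'   matrices.
#' @param mu,logvar posterior parameters, B x latent_dim.
#' @param kl_weight KL weight.
#' @return List with `mse`, `kl`, `total`.
#' @export
vae_loss <- function(x, x_hat, mu, logvar, kl_weight = 1 / 3072) {
  x <- as.matrix(x); x_hat <- as.matrix(x_hat)
  mu <- rbind(mu); logvar <- rbind(logvar)
  stopifnot(all(dim(x) == dim(x_hat)), all(dim(mu) == dim(logvar)))
  mse <- mean((x - x_hat)^2)
  kl <- mean(rowSums(0.5 * (exp(logvar) + mu^2 - 1 - logvar)))
  list(mse = mse, kl = kl, total = mse + kl_weight * kl)
}

eval_set <- function(model, X, n, batch_size) {
  L <- model$config$input_shape[1]
  D <- model$config$latent_dim
  klw <- model$config$kl_weight
  tot <- c(mse = 0, kl = 0)
  done <- 0
  while (done < n) {
    b <- min(batch_size, n - done)
    sidx <- (done + 1):(done + b)
    rows <- rep((sidx - 1) * L, each = L) + seq_len(L)
    Xb <- X[rows, , drop = FALSE]
    fw <- vae_fwd(model, Xb, b, matrix(0, b, D))
    l <- vae_fwd_loss(fw, Xb, klw)
    tot <- tot + c(l$mse, l$kl) * b
    done <- done + b
  }
  out <- tot / n
  list(mse = out[["mse"]], kl = out[["kl"]],
       total = out[["mse"]] + klw * out[["kl"]])
}

#' Train a VAE
#'
#' Adam optimization of the total loss on the training epochs, with
#' early stopping on the test-set total loss (patience from the config,
#' best weights restored). Train and test sets must come from disjoint
#' subjects; this function does not check subject identity, see
#' [make_split_plan()].
#'
#' @param model an untrained or trained `vae_model`.
#' @param epochs_train,epochs_test training and test epochs (lists of
#'   [gait_epoch()]s / matrices, or n x 512 x 6 arrays).
#' @param config optional [vae_config()] override (defaults to the
#'   model's).
#' @param verbose print per-epoch losses.
#' @return The trained `vae_model`; `model$report` holds the per-epoch
#'   loss table (`train_mse`, `train_kl`, `train_total`, `test_*`) and
#'   `best_epoch`.
#' @export
train_vae <- function(model, epochs_train, epochs_test = NULL,
                      config = model$config, verbose = FALSE) {
  stopifnot(inherits(model, "vae_model"))
  tr <- epochs_to_matrix(epochs_train, config$input_shape)
  if (tr$n < 1) stop("empty training set")
  te <- if (!is.null(epochs_test)) {
    epochs_to_matrix(epochs_test, config$input_shape)
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed + 1L)
  L <- config$input_shape[1]
  D <- config$latent_dim
  klw <- config$kl_weight
  state <- adam_init(model$params)
  best <- list(total = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  report <- vector("list", config$max_epochs)
  for (ep in seq_len(config$max_epochs)) {
    ord <- sample.int(tr$n)
    done <- 0
    acc_loss <- c(mse = 0, kl = 0)
    while (done < tr$n) {
      b <- min(config$batch_size, tr$n - done)
      sidx <- ord[(done + 1):(done + b)]
      rows <- rep((sidx - 1) * L, each = L) + seq_len(L)
      Xb <- tr$X[rows, , drop = FALSE]
      eps <- matrix(rnorm(b * D), b, D)
      fw <- vae_fwd(model, Xb, b, eps)
      l <- vae_fwd_loss(fw, Xb, klw)
      acc_loss <- acc_loss + c(l$mse, l$kl) * b
      grads <- vae_bwd(model, fw, Xb, eps, klw)
      upd <- adam_step(model$params, grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
      done <- done + b
    }
    # running training loss over the epoch's minibatches (sampled eps)
    tr_l <- list(mse = acc_loss[["mse"]] / tr$n, kl = acc_loss[["kl"]] / tr$n)
    tr_l$total <- tr_l$mse + klw * tr_l$kl
    te_l <- if (!is.null(te)) eval_set(model, te$X, te$n, config$batch_size)
    monitor <- if (!is.null(te)) te_l$total else tr_l$total
    report[[ep]] <- data.frame(
      epoch = ep, train_mse = tr_l$mse, train_kl = tr_l$kl,
      train_total = tr_l$total,
      test_mse = if (!is.null(te)) te_l$mse else NA_real_,
      test_kl = if (!is.null(te)) te_l$kl else NA_real_,
      test_total = if (!is.null(te)) te_l$total else NA_real_)
    if (verbose) {
      message(sprintf("epoch %3d train %.6f test %s", ep, tr_l$total,
                      if (!is.null(te)) sprintf("%.6f", te_l$total) else "-"))
    }
    if (monitor < best$total - config$min_delta) {
      best <- list(total = monitor, params = model$params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$report <- list(history = do.call(rbind, report[!vapply(report, is.null, logical(1))]),
                       best_epoch = best$epoch)
  model
}

#' Encode epochs to latent codes
#'
#' Deterministic inference: the latent "score" of an epoch is the
#' posterior mean (no sampling).
#'
#' @param model a `vae_model`.
#' @param epochs epochs in any form accepted by [train_vae()].
#' @param batch_size inference batch size.
#' @return A `latent_code` list: `mu` and `logvar` (n x latent_dim
#'   matrices) and `score` (identical to `mu`).
#' @export
vae_encode <- function(model, epochs, batch_size = 256) {
  stopifnot(inherits(model, "vae_model"))
  xx <- epochs_to_matrix(epochs, model$config$input_shape)
  L <- model$config$input_shape[1]
  D <- model$config$latent_dim
  mu <- matrix(0, xx$n, D); lv <- matrix(0, xx$n, D)
  done <- 0
  while (done < xx$n) {
    b <- min(batch_size, xx$n - done)
    sidx <- (done + 1):(done + b)
    rows <- rep((sidx - 1) * L, each = L) + seq_len(L)
    fw <- vae_fwd(model, xx$X[rows, , drop = FALSE], b, matrix(0, b, D))
    mu[sidx, ] <- fw$mu
    lv[sidx, ] <- fw$lv
    done <- done + b
  }
  colnames(mu) <- colnames(lv) <- paste0("L", seq_len(D) - 1)
  structure(list(mu = mu, logvar = lv, score = mu), class = "latent_code")
}

# Decode latent vectors (B x D) to signals ((B*L) x C).
vae_decode <- function(model, z) {
  z <- rbind(z)
  p <- model$params
  cfg <- model$config
  B <- nrow(z); L <- cfg$input_shape[1]; f <- cfg$filters
  mp <- vae_maps(model, B)
  hg <- tanh(sweep(z %*% p$d0_W, 2, p$d0_b, "+"))
  u3 <- unflatten_seq(hg, B, L / 8, f[3])
  d1 <- tanh(tconv_fwd(u3, p$t1_W, p$t1_b, mp$u1, mp$s1)$Y)
  d2 <- tanh(tconv_fwd(d1, p$t2_W, p$t2_b, mp$u2, mp$s2)$Y)
  tanh(tconv_fwd(d2, p$t3_W, p$t3_b, mp$u3, mp$s3)$Y)
}

#' Reconstruct epochs through the VAE
#'
#' Encodes to the posterior mean and decodes back (deterministic).
#'
#' @inheritParams vae_encode
#' @return For a single epoch, a 512 x 6 matrix; otherwise an
#'   n x 512 x 6 array.
#' @export
vae_reconstruct <- function(model, epochs, batch_size = 256) {
  xx <- epochs_to_matrix(epochs, model$config$input_shape)
  code <- vae_encode(model, epochs, batch_size)
  L <- model$config$input_shape[1]; C <- model$config$input_shape[2]
  out <- array(0, c(xx$n, L, C))
  done <- 0
  while (done < xx$n) {
    b <- min(batch_size, xx$n - done)
    sidx <- (done + 1):(done + b)
    dec <- vae_decode(model, code$mu[sidx, , drop = FALSE])
    out[sidx, , ] <- aperm(array(dec, c(L, b, C)), c(2, 1, 3))
    done <- done + b
  }
  if (xx$n == 1) {
    m <- out[1, , ]
    colnames(m) <- IMU_CHANNELS
    return(m)
  }
  out
}

#' Perturb one latent dimension and decode
#'
#' The latent-exploration primitive: decode a latent code with one
#' dimension shifted by `delta` and return the resulting signal, to
#' inspect what that latent feature encodes. `delta = 0` reproduces the
#' plain reconstruction.
#'
#' @param model a `vae_model`.
#' @param code a `latent_code` (single row used) or a length-D numeric.
#' @param dim latent dimension index (1-based).
#' @param delta shift added to `code$mu[dim]`.
#' @return 512 x 6 decoded signal matrix (normalized scale).
#' @export
perturb_and_decode <- function(model, code, dim, delta) {
  mu <- if (inherits(code, "latent_code")) code$mu[1, ] else as.numeric(code)
  stopifnot(dim >= 1, dim <= length(mu))
  mu[dim] <- mu[dim] + delta
  dec <- vae_decode(model, matrix(mu, 1))
  colnames(dec) <- IMU_CHANNELS
  dec
}

#' Reconstruction error in sensor units
#'
#' Mean absolute reconstruction error per epoch, reported on the
#' normalized scale and unstandardized back to sensor units (x8 g for
#' the accelerometer channels, x500 deg/s for the gyroscope channels).
#'
#' @inheritParams vae_encode
#' @return Data frame with per-epoch `mae_norm`, `mae_acc_g`,
#'   `mae_gyr_dps` and `mse_norm`.
#' @export
reconstruction_error <- function(model, epochs, batch_size = 256) {
  xx <- epochs_to_matrix(epochs, model$config$input_shape)
  rec <- vae_reconstruct(model, epochs, batch_size)
  L <- model$config$input_shape[1]; C <- model$config$input_shape[2]
  if (xx$n == 1) rec <- array(rec, c(1, L, C))
  out <- data.frame(epoch = seq_len(xx$n), mae_norm = NA_real_,
                    mae_acc_g = NA_real_, mae_gyr_dps = NA_real_,
                    mse_norm = NA_real_)
  for (i in seq_len(xx$n)) {
    rows <- (i - 1) * L + seq_len(L)
    err <- xx$X[rows, , drop = FALSE] - rec[i, , ]
    out$mae_norm[i] <- mean(abs(err))
    out$mae_acc_g[i] <- mean(abs(err[, 1:3])) * ACC_RANGE_G
    out$mae_gyr_dps[i] <- mean(abs(err[, 4:6])) * GYR_RANGE_DPS
    out$mse_norm[i] <- mean(err^2)
  }
  out
}

#' Participant-level cross-validation split plan
#'
#' Shuffles the subjects once, partitions them into `n_folds` balanced
#' validation folds (every subject validates exactly once), and splits
#' the remaining subjects of each fold 7:2 into training and test sets —
#' an overall 70/20/10 participant-level ratio.
#'
#' @param subject_ids character vector of unique subject ids.
#' @param n_folds number of folds (default 10).
#' @param seed shuffle seed.
#' @return List of folds; each fold has `fold_id`, `train_subjects`,
#'   `test_subjects`, `validation_subjects`.
#' @export
make_split_plan <- function(subject_ids, n_folds = 10, seed = 1) {
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  stopifnot(n >= n_folds)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  shuffled <- sample(subject_ids)
  fold_of <- rep(seq_len(n_folds), length.out = n)
  lapply(seq_len(n_folds), function(f) {
    val <- shuffled[fold_of == f]
    rest <- shuffled[fold_of != f]
    n_train <- round(length(rest) * 7 / 9)
    list(fold_id = f,
         train_subjects = rest[seq_len(n_train)],
         test_subjects = rest[(n_train + 1):length(rest)],
         validation_subjects = val)
  })
}

#' Per-group reconstruction error
#'
#' Computes the per-epoch reconstruction MSE and summarizes it by group
#' (e.g. a stroke-trained model evaluated on held-out stroke epochs
#' versus healthy epochs, whose different signal characteristics show up
#' as a higher error).
#'
#' @param model a trained `vae_model`.
#' @param epochs epochs in any accepted form.
#' @param groups character vector, one group label per epoch.
#' @param z_normalize add a per-group z-normalized error column (for
#'   distribution plots).
#' @return List with `per_epoch` (data frame: group, mse, optionally
#'   mse_z) and `summary` (group means/medians/n).
#' @export
reconstruction_error_by_group <- function(model, epochs, groups,
                                          z_normalize = FALSE) {
  err <- reconstruction_error(model, epochs)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(err))
  if (any(table(groups) == 0) || length(unique(groups)) < 1) {
    stop("empty group")
  }
  per <- data.frame(group = groups, mse = err$mse_norm)
  if (z_normalize) {
    per$mse_z <- stats::ave(per$mse, per$group,
                            FUN = function(x) (x - mean(x)) / sd(x))
  }
  summ <- do.call(rbind, lapply(split(per$mse, per$group), function(x) {
    data.frame(mean_mse = mean(x), median_mse = stats::median(x),
               n = length(x))
  }))
  summ$group <- rownames(summ)
  rownames(summ) <- NULL
  list(per_epoch = per, summary = summ[, c("group", "mean_mse",
                                           "median_mse", "n")])
}

#' Save / load a VAE model
#'
#' Runtime serialization of the model weights and config (RDS).
#'
#' @param model a `vae_model`.
#' @param path file path.
#' @export
save_vae <- function(model, path) {
  obj <- model
  obj$cache <- NULL
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  obj <- readRDS(path)
  obj$cache <- new.env(parent = emptyenv())
  obj
}
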