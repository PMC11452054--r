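# Unit tests run on a reduced architecture (shorter input, few filters)
# so each forward/backward pass is milliseconds; the full-size behavior
# is exercised by the acceptance suite.
tiny_cfg <- function(max_epochs = 30, seed = 3) {
  vae_config(input_shape = c(64, 6), filters = c(4, 6, 8), latent_dim = 5,
             batch_size = 8, max_epochs = max_epochs,
             early_stop_patience = 5, seed = seed)
}

tiny_data <- function(n = 64, seed = 1, freq = 3) {
  set.seed(seed)
  arr <- array(0, c(n, 64, 6))
  t <- seq(0, 1, length.out = 64)
  for (i in seq_len(n)) {
    ph <- runif(1, 0, 2 * pi)
    amp <- runif(1, 0.2, 0.8)
    for (c in 1:6) {
      arr[i, , c] <- amp * sin(2 * pi * freq * t + ph + c / 2) +
        rnorm(64, 0, 0.02)
    }
  }
  arr
}

test_that("forward pass respects the shape contract and is deterministic", {
  m <- build_vae(tiny_cfg())
  x <- tiny_data(1)[1, , ]
  code <- vae_encode(m, x)
  expect_equal(dim(code$mu), c(1, 5))
  expect_identical(code$score, code$mu)
  rec <- vae_reconstruct(m, x)
  expect_equal(dim(rec), c(64, 6))
  # same epoch twice: identical latent code
  code2 <- vae_encode(m, x)
  expect_identical(code$mu, code2$mu)
  # same seed, fresh build: identical weights
  m2 <- build_vae(tiny_cfg())
  expect_identical(m$params, m2$params)
})

test_that("the full-size architecture produces 512x6 output and 12 latents", {
  m <- build_vae(vae_config(filters = c(4, 6, 8), seed = 1))
  expect_equal(m$config$encoder_layer_nodes, c(256L, 128L, 64L))
  x <- matrix(rnorm(512 * 6, 0, 0.1), 512, 6)
  code <- vae_encode(m, x)
  expect_equal(dim(code$mu), c(1, 12))
  expect_equal(dim(vae_reconstruct(m, x)), c(512, 6))
})

test_that("loss decomposition follows its closed forms", {
  x <- matrix(rnorm(512 * 6), 512, 6)
  mu0 <- rep(0, 12); lv0 <- rep(0, 12)
  # identity reconstruction with a standard-normal posterior: all zero
  l <- vae_loss(x, x, mu0, lv0)
  expect_equal(l$mse, 0)
  expect_equal(l$kl, 0)
  expect_equal(l$total, 0)
  # standard-normal posterior: kl exactly zero whatever the signals
  l2 <- vae_loss(x, x * 0.5, mu0, lv0)
  expect_equal(l2$kl, 0)
  expect_gt(l2$mse, 0)
  # unit mean in one dimension: kl = mu^2 / 2 = 0.5
  mu1 <- c(1, rep(0, 11))
  l3 <- vae_loss(x, x, mu1, lv0)
  expect_equal(l3$kl, 0.5)
  # decomposition holds exactly and kl is nonnegative
  set.seed(4)
  mu <- matrix(rnorm(24), 2); lv <- matrix(rnorm(24, 0, 0.5), 2)
  xb <- matrix(rnorm(2 * 512 * 6), 1024, 6)
  l4 <- vae_loss(xb, xb * 0.9, mu, lv, kl_weight = 0.25)
  expect_gte(l4$kl, 0)
  expect_equal(l4$total, l4$mse + 0.25 * l4$kl, tolerance = 1e-15)
})

test_that("the reparameterized sample is mu + exp(logvar/2) * eps", {
  m <- build_vae(tiny_cfg())
  x <- tiny_data(2, seed = 5)
  xx <- gaitlatent:::epochs_to_matrix(x, c(64, 6))
  eps0 <- matrix(0, 2, 5)
  fw <- gaitlatent:::vae_fwd(m, xx$X, 2, eps0)
  expect_equal(fw$z, fw$mu)
  eps1 <- matrix(1, 2, 5)
  fw1 <- gaitlatent:::vae_fwd(m, xx$X, 2, eps1)
  expect_equal(fw1$z, fw1$mu + exp(fw1$lv / 2), tolerance = 1e-12)
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  arr <- tiny_data(80)
  m <- build_vae(tiny_cfg())
  x0 <- gaitlatent:::epochs_to_matrix(arr, c(64, 6))
  l0 <- gaitlatent:::eval_set(m, x0$X, x0$n, 8)
  mt <- train_vae(m, arr[1:64, , ], arr[65:80, , ])
  expect_true(mt$trained)
  hist <- mt$report$history
  expect_lt(hist$train_mse[nrow(hist)], l0$mse)
  expect_lt(hist$train_total[nrow(hist)], hist$train_total[1])
  # kl stays positive (regularization active) but bounded
  expect_gt(hist$train_kl[nrow(hist)], 0)
  expect_lt(hist$train_kl[nrow(hist)], 20)
  # bit-reproducible under identical seeds
  mt2 <- train_vae(build_vae(tiny_cfg()), arr[1:64, , ], arr[65:80, , ])
  expect_equal(mt$params, mt2$params, tolerance = 1e-12)
  expect_equal(mt$report$history$test_total, mt2$report$history$test_total,
               tolerance = 1e-12)
  # empty training set is an error
  expect_error(train_vae(build_vae(tiny_cfg()), list()), "empty|length")
})

test_that("perturbing a latent dimension by zero reproduces the reconstruction", {
  arr <- tiny_data(40)
  m <- train_vae(build_vae(tiny_cfg(max_epochs = 5)), arr)
  x <- arr[1, , ]
  code <- vae_encode(m, x)
  rec <- vae_reconstruct(m, x)
  pert0 <- perturb_and_decode(m, code, dim = 2, delta = 0)
  expect_equal(unname(pert0), unname(rec), tolerance = 1e-12)
  pert <- perturb_and_decode(m, code, dim = 2, delta = 2)
  expect_false(isTRUE(all.equal(unname(pert), unname(rec))))
})

test_that("reconstruction error is reported in normalized and sensor units", {
  m <- build_vae(tiny_cfg())
  arr <- tiny_data(3)
  err <- reconstruction_error(m, arr)
  expect_equal(nrow(err), 3)
  # unit bookkeeping: acc errors scale by 8 g, gyro errors by 500 deg/s
  xx <- gaitlatent:::epochs_to_matrix(arr, c(64, 6))
  rec <- vae_reconstruct(m, arr)
  d1 <- abs(xx$X[1:64, ] - rec[1, , ])
  expect_equal(err$mae_acc_g[1], mean(d1[, 1:3]) * 8, tolerance = 1e-12)
  expect_equal(err$mae_gyr_dps[1], mean(d1[, 4:6]) * 500, tolerance = 1e-12)
})

test_that("split plans partition subjects at participant level", {
  ids <- sprintf("P%03d", 1:10)
  plan <- make_split_plan(ids, n_folds = 10, seed = 2)
  expect_length(plan, 10)
  val_sizes <- vapply(plan, function(f) length(f$validation_subjects),
                      integer(1))
  expect_true(all(val_sizes == 1))
  expect_setequal(unlist(lapply(plan, `[[`, "validation_subjects")), ids)
  # no subject appears in two sets of the same fold (leakage assertion)
  for (f in plan) {
    sets <- list(f$train_subjects, f$test_subjects, f$validation_subjects)
    expect_equal(length(unlist(sets)), length(unique(unlist(sets))))
    expect_setequal(unlist(sets), ids)
  }
  # 107 subjects: balanced folds of 10 or 11, ~70/20 train/test
  ids2 <- sprintf("Q%03d", 1:107)
  plan2 <- make_split_plan(ids2, seed = 5)
  vs <- vapply(plan2, function(f) length(f$validation_subjects), integer(1))
  expect_true(all(vs %in% c(10L, 11L)))
  expect_setequal(unlist(lapply(plan2, `[[`, "validation_subjects")), ids2)
  tr <- vapply(plan2, function(f) length(f$train_subjects), integer(1))
  expect_true(all(abs(tr - 0.7 * 107) <= 2))
})

test_that("reconstruction error by group summarizes and validates input", {
  m <- build_vae(tiny_cfg())
  arr <- tiny_data(6)
  res <- reconstruction_error_by_group(m, arr, rep(c("a", "b"), each = 3),
                                       z_normalize = TRUE)
  expect_equal(sort(res$summary$group), c("a", "b"))
  expect_equal(res$summary$n, c(3, 3))
  expect_true(all(is.finite(res$per_epoch$mse_z)))
  expect_error(reconstruction_error_by_group(m, arr, rep("a", 5)))
})

test_that("models round-trip through serialization", {
  dir <- withr::local_tempdir()
  m <- build_vae(tiny_cfg())
  p <- file.path(dir, "m.rds")
  save_vae(m, p)
  m2 <- load_vae(p)
  expect_identical(m$params, m2$params)
  x <- tiny_data(1)[1, , ]
  expect_identical(vae_encode(m, x)$mu, vae_encode(m2, x)$mu)
})
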