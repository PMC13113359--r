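test_that("augmentation respects identity, involution and determinism", {
  s <- generate_sample(test_syn_config(), seed = 3)

  ident <- augment_config(hflip_prob = 0, vflip_prob = 0, rotation_max = 0,
                          brightness_jitter = 0, contrast_jitter = 0)
  expect_identical(augment_sample(s, ident, seed = 1), s)

  off <- augment_config(enabled = FALSE)
  expect_identical(augment_sample(s, off, seed = 1), s)

  # horizontal flip applied twice restores the sample
  hf <- augment_config(hflip_prob = 1, vflip_prob = 0, rotation_max = 0,
                       brightness_jitter = 0, contrast_jitter = 0)
  twice <- augment_sample(augment_sample(s, hf, seed = 1), hf, seed = 2)
  expect_equal(twice$image, s$image)
  expect_equal(twice$fov_mask, s$fov_mask)

  # same seed -> identical augmented output; masks move with the image
  full <- augment_config()
  a1 <- augment_sample(s, full, seed = 9)
  a2 <- augment_sample(s, full, seed = 9)
  expect_identical(a1, a2)
  expect_identical(a1$labels, s$labels)
  expect_identical(a1$group_id, s$group_id)
})

test_that("the learning-rate schedule is the exact exponential decay", {
  cfg1 <- train_config(lr0 = 0.05, decay = 1)
  expect_equal(sapply(0:20, lr_at, config = cfg1), rep(0.05, 21))

  cfg2 <- train_config(lr0 = 0.1, decay = 0.5)
  expect_equal(lr_at(3, cfg2), 0.0125)

  cfg3 <- train_config(lr0 = 1e-3, decay = 0.97)
  rates <- lr_at(0:999, cfg3)
  expect_equal(rates, 1e-3 * 0.97^(0:999))
  expect_true(all(diff(rates) <= 0))
})

test_that("plain SGD reproduces the literal update rule exactly", {
  g <- tiny_grid()
  cfg <- tiny_encoder_config(g, L = 1L)
  model <- fundus_model(cfg, 2, screen_dim = 4, seed = 1)
  Z <- random_patches(g, seed = 2)
  nb <- fundusformer:::support_mask_int(cfg)
  out <- fundusformer:::model_grad_cpp(Z, model$params, model$head, c(1, 0),
                                       alpha_schedule(cfg), nb,
                                       cfg$fusion_depths, cfg$n_heads, FALSE)
  lr <- 0.05
  upd <- optimizer_step(model, out$grads,
                        lr, train_config(optimizer = "plain_sgd"), NULL)
  for (pt in fundusformer:::leaf_paths(model)) {
    theta0 <- fundusformer:::get_leaf(model, pt)
    theta1 <- fundusformer:::get_leaf(upd$model, pt)
    gr <- fundusformer:::grad_leaf(out$grads, pt)
    if (is.null(dim(theta0))) gr <- as.numeric(gr)
    expect_equal(theta1, theta0 - lr * gr, tolerance = 0)
  }
})

test_that("zero learning rate leaves every parameter untouched", {
  ds <- generate_dataset(test_syn_config(), 12, split_fracs = c(1, 0, 0),
                         seed = 4)
  g <- patch_grid(32, 8)
  cfg <- encoder_config(2, 16, 2, g, fusion_depths = c(1, 2))
  model <- fundus_model(cfg, 2, screen_dim = 8, seed = 5)
  fit <- train_model(model, ds, train_config(epochs = 2, lr0 = 0,
                                             early_stop_patience = 10,
                                             seed = 1))
  for (pt in fundusformer:::leaf_paths(model)) {
    expect_equal(fundusformer:::get_leaf(fit$model, pt),
                 fundusformer:::get_leaf(model, pt))
  }
})

test_that("training is deterministic and its loss decreases early", {
  ds <- generate_dataset(test_syn_config(), 16, split_fracs = c(1, 0, 0),
                         seed = 6)
  g <- patch_grid(32, 8)
  cfg <- encoder_config(2, 16, 2, g, fusion_depths = c(1, 2),
                        stabilized = TRUE)
  tc <- function(seed) train_config(epochs = 5, batch_size = 8, lr0 = 1e-3,
                                    decay = 1, early_stop_patience = 10,
                                    seed = seed)
  # same seed twice -> identical loss history
  f1 <- train_model(fundus_model(cfg, 2, screen_dim = 8, seed = 1), ds, tc(3))
  f2 <- train_model(fundus_model(cfg, 2, screen_dim = 8, seed = 1), ds, tc(3))
  expect_identical(f1$history, f2$history)

  # loss non-increasing over the first 5 epochs in at least 4 of 5 seeds
  ok <- 0
  for (seed in 1:5) {
    f <- train_model(fundus_model(cfg, 2, screen_dim = 8, seed = seed), ds,
                     tc(seed))
    if (all(diff(f$history$train_loss) <= 1e-6)) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("early stopping returns the best-validation snapshot", {
  ds <- generate_dataset(test_syn_config(), 24, split_fracs = c(0.5, 0.5, 0),
                         seed = 7)
  g <- patch_grid(32, 8)
  cfg <- encoder_config(2, 16, 2, g, fusion_depths = c(1, 2),
                        stabilized = TRUE)
  fit <- train_model(fundus_model(cfg, 2, screen_dim = 8, seed = 2), ds,
                     train_config(epochs = 8, batch_size = 8, lr0 = 2e-3,
                                  early_stop_patience = 3, seed = 1))
  expect_equal(min(fit$history$val_loss),
               fit$history$val_loss[fit$best_epoch])
  # recomputing the returned model's validation loss reproduces the optimum
  val_patches <- lapply(ds$validation, function(s) {
    preprocess_image(s, fit$stats, g)$patches
  })
  y_val <- fundusformer:::dataset_labels(ds$validation)
  recomputed <- fundusformer:::mean_loss(fit$model, val_patches, y_val)
  expect_equal(recomputed, min(fit$history$val_loss), tolerance = 1e-9)
})

test_that("learnable monotone alpha stays monotone through training", {
  ds <- generate_dataset(test_syn_config(), 16, split_fracs = c(1, 0, 0),
                         seed = 8)
  g <- patch_grid(32, 8)
  cfg <- encoder_config(3, 16, 2, g, alpha_mode = "learnable_monotone",
                        fusion_depths = c(2, 3), stabilized = TRUE)
  fit <- train_model(fundus_model(cfg, 2, screen_dim = 8, seed = 3), ds,
                     train_config(epochs = 4, batch_size = 8, lr0 = 2e-3,
                                  early_stop_patience = 10, seed = 2))
  a <- alpha_schedule(cfg, fit$model$params)
  expect_true(all(a >= 0 & a <= 1))
  expect_true(all(diff(a) > 0))
  # alpha parameters actually moved
  fresh <- fundus_model(cfg, 2, screen_dim = 8, seed = 3)
  expect_false(identical(fit$model$params$alpha_base,
                         fresh$params$alpha_base))
})
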