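test_that("metrics reach their closed forms on perfect predictions", {
  y <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0), 4, 2)
  p <- y * 0.8 + 0.1
  m <- compute_metrics(y, p, y)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$auroc, 1)
})

test_that("AUROC is the pair-counting rank statistic with tie half-credit", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # 3 concordant of 4 pairs
  expect_equal(auroc(c(0.6, 0.4, 0.5, 0.3), c(1, 1, 0, 0)), 0.75)
  # ties get half credit
  expect_equal(auroc(c(0.5, 0.5), c(1, 0)), 0.5)
  # exhaustive agreement with the pair-counting oracle at n <= 12
  withr::with_seed(1, {
    for (i in 1:50) {
      n <- sample(4:12, 1)
      s <- round(runif(n), 1)  # coarse grid forces ties
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      expect_equal(auroc(s, y), oracle_auroc(s, y), tolerance = 1e-12)
    }
  })
  expect_true(is.na(auroc(c(0.1, 0.2), c(1, 1))))
})

test_that("AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(2, {
    s <- runif(60); y <- rbinom(60, 1, 0.4)
  })
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("macro metrics are unweighted class means, invariant to relabeling", {
  withr::with_seed(3, {
    y <- matrix(rbinom(60, 1, 0.4), 20, 3)
    p <- matrix(runif(60), 20, 3)
    d <- (p >= 0.5) * 1
  })
  m <- compute_metrics(d, p, y)
  expect_equal(m$macro_f1, mean(m$per_class$f1))
  perm <- c(2, 3, 1)
  m2 <- compute_metrics(d[, perm], p[, perm], y[, perm])
  expect_equal(m2$macro_f1, m$macro_f1)
  expect_equal(m2$accuracy, m$accuracy)

  # single-class column: AUROC excluded with a warning
  y1 <- y; y1[, 2] <- 1
  expect_warning(m3 <- compute_metrics(d, p, y1), "AUROC undefined")
  expect_equal(m3$auroc, mean(m3$per_class$auroc, na.rm = TRUE))
})

test_that("every perturbation kind is the identity at level zero", {
  s <- generate_sample(test_syn_config(), seed = 4)
  for (kind in c("brightness_down", "brightness_up", "contrast_down",
                 "gaussian_blur", "gaussian_noise")) {
    spec <- perturbation_spec(kind, c(0, 0.3))
    expect_identical(perturb_image(s$image, spec, 1, s$fov_mask), s$image)
  }
})

test_that("brightness scaling composes multiplicatively inside the FOV", {
  s <- generate_sample(test_syn_config(noise_sd = 0), seed = 5)
  img <- s$image * 0.45  # keep products below 1 so clipping is inactive
  down <- perturb_image(img, perturbation_spec("brightness_down", 0.5), 1,
                        s$fov_mask)
  up <- perturb_image(down, perturbation_spec("brightness_up", 1), 1,
                      s$fov_mask)
  expect_equal(up, img, tolerance = 1e-12)
  # outside the FOV nothing changes
  outside <- rep(s$fov_mask == 0, 3)
  expect_identical(down[outside], img[outside])
})

test_that("contrast reduction blends toward the FOV mean and noise is seeded", {
  s <- generate_sample(test_syn_config(), seed = 6)
  spec <- perturbation_spec("contrast_down", 1)
  flat <- perturb_image(s$image, spec, 1, s$fov_mask)
  m <- mean(s$image[rep(s$fov_mask == 1, 3)])
  inside <- rep(s$fov_mask == 1, 3)
  expect_true(all(abs(flat[inside] - m) < 1e-12))

  nspec <- perturbation_spec("gaussian_noise", 0.1, seed = 3)
  n1 <- perturb_image(s$image, nspec, 1, s$fov_mask)
  n2 <- perturb_image(s$image, nspec, 1, s$fov_mask)
  expect_identical(n1, n2)
  expect_false(identical(n1, s$image))
})

test_that("a constant predictor is perfectly stable with zero drop", {
  ds <- generate_dataset(test_syn_config(), 12, split_fracs = c(0.5, 0, 0.5),
                         seed = 7)
  g <- patch_grid(32, 8)
  cfg <- encoder_config(1, 16, 2, g, fusion_depths = 1L)
  model <- fundus_model(cfg, 2, screen_dim = 8, seed = 1)
  # zero head weights force probability 0.5 for every class and sample
  model$head$class_weights[] <- 0
  stats <- fit_channel_stats(ds$train)
  rob <- robustness_suite(model, ds$test,
                          list(perturbation_spec("gaussian_noise", c(0.05, 0.2))),
                          stats)
  expect_equal(rob$stability_index, 100)
  expect_equal(rob$drops$accuracy_drop, 0)
  expect_true(all(rob$per_spec$accuracy == rob$clean$accuracy))
})

test_that("alignment fractions partition unity for arbitrary attention", {
  g <- patch_grid(32, 8)
  s <- generate_sample(test_syn_config(), seed = 9)
  # make sure there is a lesion; rerun seeds until one appears
  seed <- 9
  while (!any(s$lesion_mask == 1)) { seed <- seed + 1; s <- generate_sample(test_syn_config(), seed = seed) }
  withr::with_seed(10, {
    for (i in 1:20) {
      a <- matrix(rexp(16 * 16), 16, 16); a <- a / rowSums(a)
      al <- attention_alignment(list(list(mixed = a)), s$lesion_mask,
                                s$fov_mask, g)
      expect_equal(al$relevant_region_coverage + al$diffuse_attention +
                   al$misaligned_focus, 1, tolerance = 1e-9)
      expect_true(al$relevant_region_coverage >= 0)
      expect_true(al$misaligned_focus >= 0)
    }
  })
})

test_that("uniform attention coverage equals the lesion patch fraction", {
  g <- patch_grid(32, 8)
  s <- generate_sample(test_syn_config(), seed = 21)
  seed <- 21
  while (!any(s$lesion_mask == 1)) { seed <- seed + 1; s <- generate_sample(test_syn_config(), seed = seed) }
  unif <- matrix(1 / 16, 16, 16)
  al <- attention_alignment(list(list(mixed = unif)), s$lesion_mask,
                            s$fov_mask, g)
  expect_equal(al$relevant_region_coverage, al$lesion_patch_fraction,
               tolerance = 1e-12)

  # all saliency concentrated on one lesion patch -> coverage 1
  cats <- fundusformer:::patch_categories(s$lesion_mask, s$fov_mask, g)
  onehot <- matrix(0, 16, 16)
  onehot[, which(cats$lesion)[1]] <- 1
  al2 <- attention_alignment(list(list(mixed = onehot)), s$lesion_mask,
                             s$fov_mask, g)
  expect_equal(al2$relevant_region_coverage, 1)
})

test_that("samples without lesions are excluded from alignment with a count", {
  cls <- default_lesion_classes(32L)
  for (i in seq_along(cls)) cls[[i]]$prevalence <- c(1, 0)[i]
  cfg <- test_syn_config(lesion_classes = cls)
  samples <- lapply(1:4, function(i) generate_sample(cfg, seed = 30 + i))
  empty <- generate_sample(test_syn_config(lesion_classes = {
    z <- cls; z[[1]]$prevalence <- 0; z
  }), seed = 50)
  g <- patch_grid(32, 8)
  ec <- encoder_config(1, 16, 2, g, fusion_depths = 1L)
  model <- fundus_model(ec, 2, screen_dim = 8, seed = 1)
  stats <- fit_channel_stats(samples)
  al <- alignment_suite(model, c(samples, list(empty)), stats)
  expect_equal(al$n_excluded, 1L)
  expect_equal(al$n_used, 4L)
})

test_that("retention is the uncapped cross-to-in-domain ratio", {
  expect_equal(retention(0.8, 0.8), 100)
  expect_equal(retention(1.0, 0.8), 80)
  expect_equal(retention(0.5, 0.6), 120)
  expect_error(retention(0, 0.5), "zero")
})
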