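test_that("token embedding equals projection plus positional term", {
  g <- tiny_grid()
  cfg <- tiny_encoder_config(g, L = 1L, E = 8L, heads = 2L)
  p <- init_encoder_params(cfg, seed = 1)

  # zero patches + zero positions -> zero tokens
  expect_equal(embed_tokens(matrix(0, 9, g$patch_dim), p),
               matrix(0, 9, 8))

  # identity-like projection with E = patch_dim reproduces the patches
  g2 <- patch_grid(4, 2, n_channels = 1)  # patch_dim 4
  cfg2 <- encoder_config(1, 4, 1, g2, fusion_depths = 1L)
  p2 <- init_encoder_params(cfg2, seed = 1)
  p2$patch_projection <- diag(4)
  Z2 <- withr::with_seed(2, matrix(rnorm(16), 4, 4))
  expect_equal(embed_tokens(Z2, p2), Z2)

  # random case against an explicit per-element loop
  Z <- random_patches(g, seed = 3)
  got <- embed_tokens(Z, p)
  for (i in 1:9) {
    for (a in 1:8) {
      expect_equal(got[i, a],
                   sum(p$patch_projection[a, ] * Z[i, ]) + p$positional_table[i, a],
                   tolerance = 1e-6)
    }
  }
  expect_error(embed_tokens(Z[1:5, ], p), "positional table")
})

test_that("neighborhoods follow Chebyshev geometry with border truncation", {
  g <- tiny_grid()  # 3x3 token grid
  expect_equal(neighborhood_indices(5, g, 0), 5L)
  expect_setequal(neighborhood_indices(5, g, 1), 1:9)
  expect_setequal(neighborhood_indices(1, g, 1), c(1L, 2L, 4L, 5L))
  expect_setequal(neighborhood_indices(5, g, 10), 1:9)
  # agreement with the enumeration oracle on a rectangular-ish case
  g4 <- patch_grid(16, 4)
  for (i in c(1, 6, 16)) {
    for (r in 0:3) {
      expect_setequal(neighborhood_indices(i, g4, r),
                      oracle_neighborhood(i, 4, 4, r))
    }
  }
  # mask rows match the index sets
  m <- neighborhood_mask(g, 1)
  for (i in 1:9) expect_setequal(which(m[i, ]), neighborhood_indices(i, g, 1))
})

test_that("attention rows are the softmax of scaled dot products", {
  # identical keys -> uniform weights over the support
  q <- withr::with_seed(1, matrix(rnorm(12), 4, 3))
  k <- matrix(1, 4, 3)
  a <- attention_rows(q, k)
  expect_equal(a, matrix(0.25, 4, 4))

  sup <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 4, byrow = TRUE)
  al <- attention_rows(q, k, sup)
  expect_equal(al[, 1:2], matrix(0.5, 4, 2))
  expect_true(all(al[, 3:4] == 0))

  # single token
  expect_equal(attention_rows(matrix(1, 1, 2), matrix(2, 1, 2)),
               matrix(1, 1, 1))

  # random case vs the two-loop oracle, plus logit-shift invariance
  withr::with_seed(4, {
    q <- matrix(rnorm(16), 8, 2); k <- matrix(rnorm(16), 8, 2)
  })
  a <- attention_rows(q, k)
  for (i in 1:8) {
    logits <- sapply(1:8, function(j) sum(q[i, ] * k[j, ]) / sqrt(2))
    expect_equal(a[i, ], oracle_softmax_row(logits, 1:8), tolerance = 1e-6)
    expect_equal(a[i, ], oracle_softmax_row(logits + 13.7, 1:8),
                 tolerance = 1e-6)
  }
  expect_error(attention_rows(q, k, matrix(FALSE, 8, 8)), "empty support")
})

test_that("mixed attention is an exact convex combination", {
  withr::with_seed(5, {
    a1 <- matrix(rexp(36), 6, 6); a1 <- a1 / rowSums(a1)
    a2 <- matrix(rexp(36), 6, 6); a2 <- a2 / rowSums(a2)
  })
  expect_identical(mixed_attention(a1, a2, 0), a1)
  expect_identical(mixed_attention(a1, a2, 1), a2)
  m <- mixed_attention(a1, a2, 0.37)
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  expect_error(mixed_attention(a1, a2, 1.2), "alpha")
})

test_that("an encoder layer with zero weights is the identity (residual)", {
  g <- tiny_grid()
  E <- 8
  zero_lp <- list(Wq = matrix(0, E, E), Wk = matrix(0, E, E),
                  Wv = matrix(0, E, E), Wo = matrix(0, E, E),
                  W1 = matrix(0, 2 * E, E), W2 = matrix(0, E, 2 * E))
  tok <- withr::with_seed(6, matrix(rnorm(9 * E), 9, E))
  out <- encoder_layer(tok, zero_lp, 0.5, neighborhood_mask(g, 1), n_heads = 2)
  expect_equal(out$tokens, tok)
})

test_that("encoder layers and the full encoder match the nested-loop oracle", {
  for (gridsize in c(3L, 4L)) {
    g <- patch_grid(gridsize * 4L, 4L)
    cfg <- encoder_config(2, 8, 2, g, fusion_depths = c(1, 2))
    for (seed in 1:4) {
      p <- init_encoder_params(cfg, seed = seed)
      p$positional_table <- withr::with_seed(seed, matrix(rnorm(g$n_patches * 8, 0, 0.3),
                                                          g$n_patches, 8))
      Z <- random_patches(g, seed = 100 + seed)
      got <- encode(Z, cfg, p)
      want <- oracle_encoder(Z, p, alpha_schedule(cfg), g,
                             cfg$neighborhood_radius, cfg$n_heads,
                             cfg$fusion_depths)
      expect_equal(got$fused, want$fused, tolerance = 1e-5)
      expect_equal(got$final_tokens, want$tokens, tolerance = 1e-5)
      expect_equal(got$level_pools, want$pools, tolerance = 1e-5)
      expect_equal(got$beta, want$beta, tolerance = 1e-9)
    }
  }
})

test_that("compiled forward equals the R reference bitwise-tight", {
  g <- tiny_grid()
  for (stab in c(FALSE, TRUE)) {
    cfg <- tiny_encoder_config(g, stabilized = stab)
    p <- init_encoder_params(cfg, seed = 2)
    Z <- random_patches(g, seed = 5)
    r1 <- encode(Z, cfg, p)
    r2 <- fundusformer:::encoder_forward_cpp(
      Z, p, alpha_schedule(cfg), fundusformer:::support_mask_int(cfg),
      cfg$fusion_depths, cfg$n_heads, cfg$stabilized)
    expect_equal(r1$fused, as.numeric(r2$fused), tolerance = 1e-12)
    expect_equal(r1$final_tokens, r2$final_tokens, tolerance = 1e-12)
  }
})

test_that("pooling and fusion follow their closed forms", {
  v <- c(1, -2, 3)
  expect_equal(pool_level(rbind(v, v, v)), v, ignore_attr = TRUE)
  expect_equal(pool_level(rbind(v, -v)), c(0, 0, 0), ignore_attr = TRUE)
  toks <- withr::with_seed(7, matrix(rnorm(15), 5, 3))
  expect_equal(pool_level(toks),
               sapply(1:3, function(a) mean(toks[, a])), ignore_attr = TRUE)

  pools <- rbind(c(1, 2), c(3, 4), c(5, 6))
  # one dominant logit selects its level
  f <- fuse_levels(pools, c(50, 0, 0))
  expect_equal(as.numeric(f), c(1, 2), tolerance = 1e-6)
  # equal logits average
  f2 <- fuse_levels(pools[1:2, ], c(0.3, 0.3))
  expect_equal(as.numeric(f2), c(2, 3))
  # random logits: convexity and loop agreement
  lg <- withr::with_seed(8, rnorm(3))
  f3 <- fuse_levels(pools, lg)
  beta <- attr(f3, "beta")
  expect_equal(sum(beta), 1, tolerance = 1e-9)
  expect_true(all(beta >= 0))
  expect_equal(as.numeric(f3),
               c(sum(beta * pools[, 1]), sum(beta * pools[, 2])))
})

test_that("alpha schedules are monotone within [0, 1]", {
  g <- tiny_grid()
  cfg <- encoder_config(6, 8, 2, g, fusion_depths = 6L)
  a <- alpha_schedule(cfg)
  expect_equal(a, (1:6) / 6)

  cfgl <- encoder_config(6, 8, 2, g, alpha_mode = "learnable_monotone",
                         fusion_depths = 6L)
  pl <- init_encoder_params(cfgl, seed = 1)
  al <- alpha_schedule(cfgl, pl)
  expect_true(all(al >= 0 & al <= 1))
  expect_true(all(diff(al) > 0))

  expect_equal(alpha_schedule(encoder_config(3, 8, 2, g, alpha_mode = "global_only",
                                             fusion_depths = 3L)), rep(1, 3))
  expect_equal(alpha_schedule(encoder_config(3, 8, 2, g, alpha_mode = "local_only",
                                             fusion_depths = 3L)), rep(0, 3))
})

test_that("attention maps are row-stochastic with local support everywhere", {
  g <- tiny_grid()
  cfg <- tiny_encoder_config(g, L = 2L)
  p <- init_encoder_params(cfg, seed = 3)
  Z <- random_patches(g, seed = 6)
  rep <- encode(Z, cfg, p, keep_attention = "all")
  sup <- neighborhood_mask(g, cfg$neighborhood_radius)
  for (layer in rep$attention) {
    for (h in layer) {
      for (kind in c("local", "global", "mixed")) {
        a <- h[[kind]]
        expect_true(all(a >= 0))
        expect_true(all(abs(rowSums(a) - 1) < 1e-6))
      }
      expect_true(all(h$local[!sup] == 0))
    }
  }
})

test_that("alpha endpoints reduce to pure local / pure global encoders", {
  g <- tiny_grid()
  cfg <- tiny_encoder_config(g, L = 2L)
  p <- init_encoder_params(cfg, seed = 4)
  Z <- random_patches(g, seed = 7)
  sup <- neighborhood_mask(g, 1)

  tok <- embed_tokens(Z, p)
  lp <- p$layers[[1]]
  out0 <- encoder_layer(tok, lp, 0, sup, n_heads = 2, keep_attention = TRUE)
  out1 <- encoder_layer(tok, lp, 1, sup, n_heads = 2, keep_attention = TRUE)
  for (h in 1:2) {
    expect_identical(out0$attention[[h]]$mixed, out0$attention[[h]]$local)
    expect_identical(out1$attention[[h]]$mixed, out1$attention[[h]]$global)
  }

  # global_only mode equals a radius-covering local-only encoder
  cfg_g <- encoder_config(2, 8, 2, g, alpha_mode = "global_only",
                          fusion_depths = c(1, 2))
  cfg_wide <- encoder_config(2, 8, 2, g, alpha_mode = "local_only",
                             neighborhood_radius = 5L, fusion_depths = c(1, 2))
  expect_equal(encode(Z, cfg_g, p)$fused, encode(Z, cfg_wide, p)$fused,
               tolerance = 1e-12)
})

test_that("relabeling patches with their positions leaves the encoding invariant", {
  # permuting patch order together with the positional table and the
  # neighborhood mask is a pure relabeling; the mean-pooled fused vector
  # must be identical
  g <- tiny_grid()
  cfg <- tiny_encoder_config(g, L = 2L)
  p <- init_encoder_params(cfg, seed = 5)
  p$positional_table <- withr::with_seed(11, matrix(rnorm(9 * 8, 0, 0.3), 9, 8))
  Z <- random_patches(g, seed = 8)
  perm <- withr::with_seed(9, sample(9))

  base <- encode(Z, cfg, p)

  sup <- neighborhood_mask(g, 1)[perm, perm]
  pp <- p
  pp$positional_table <- p$positional_table[perm, ]
  tok <- embed_tokens(Z[perm, ], pp)
  alphas <- alpha_schedule(cfg)
  pools <- matrix(0, 2, 8)
  for (l in 1:2) {
    out <- encoder_layer(tok, p$layers[[l]], alphas[l], sup, n_heads = 2)
    tok <- out$tokens
    pools[l, ] <- pool_level(tok)
  }
  fused <- fuse_levels(pools, p$fusion_logits)
  expect_equal(as.numeric(fused), base$fused, tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  g <- tiny_grid()
  for (stab in c(FALSE, TRUE)) {
    cfg <- encoder_config(3, 8, 2, g, fusion_depths = c(1, 3),
                          stabilized = stab)
    model <- fundus_model(cfg, 2, screen_dim = 5, seed = 3)
    model <- inflate_params(model, sd = 0.2)
    Z <- random_patches(g, seed = 10)
    y <- c(1, 0)
    nb <- fundusformer:::support_mask_int(cfg)
    al <- alpha_schedule(cfg)
    out <- fundusformer:::model_grad_cpp(Z, model$params, model$head, y, al,
                                         nb, cfg$fusion_depths, cfg$n_heads,
                                         stab)
    lossfn <- function(m) {
      f <- fundusformer:::encoder_forward_cpp(Z, m$params, al, nb,
                                              cfg$fusion_depths,
                                              cfg$n_heads, stab)
      r <- project_screening(as.numeric(f$fused), m$head)
      loss_multi(y, plogis(as.numeric(m$head$class_weights %*% r)))
    }
    eps <- 1e-5
    for (pt in fundusformer:::leaf_paths(model)) {
      th <- fundusformer:::get_leaf(model, pt)
      ks <- withr::with_seed(length(th), sample(length(th), min(3, length(th))))
      for (k in ks) {
        th1 <- th; th1[k] <- th[k] + eps
        th2 <- th; th2[k] <- th[k] - eps
        fd <- (lossfn(fundusformer:::set_leaf(model, pt, th1)) -
               lossfn(fundusformer:::set_leaf(model, pt, th2))) / (2 * eps)
        an <- fundusformer:::grad_leaf(out$grads, pt)[k]
        expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-6), 1e-4)
      }
    }
  }
})

test_that("end-to-end encode returns consistent shapes on a tiny image", {
  cfg_s <- test_syn_config()
  s <- generate_sample(cfg_s, seed = 12)
  g <- patch_grid(32, 8)
  ec <- encoder_config(2, 16, 2, g, fusion_depths = c(1, 2))
  p <- init_encoder_params(ec, seed = 1)
  stats <- fit_channel_stats(lapply(1:3, function(i) generate_sample(cfg_s, seed = i)))
  rep <- encode(s, ec, p, stats = stats, keep_attention = "final")
  expect_length(rep$fused, 16)
  expect_equal(dim(rep$level_pools), c(2L, 16L))
  expect_equal(dim(rep$final_tokens), c(16L, 16L))
  expect_equal(as.numeric(crossprod(rep$level_pools, rep$beta)),
               rep$fused, tolerance = 1e-6)
})
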