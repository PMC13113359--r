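# Small shared fixtures, all generated in code.

tiny_grid <- function(n = 3L, P = 4L) patch_grid(n * P, P)

tiny_encoder_config <- function(grid = tiny_grid(), L = 3L, E = 8L,
                                heads = 2L, ...) {
  encoder_config(L, E, heads, grid,
                 fusion_depths = unique(c(max(1L, L - 1L), L)), ...)
}

random_patches <- function(grid, seed = 1L) {
  withr::with_seed(seed,
    matrix(rnorm(grid$n_patches * grid$patch_dim), grid$n_patches,
           grid$patch_dim))
}

# A small synthetic config used across tests (32 px keeps everything fast).
test_syn_config <- function(image_size = 32L, ...) {
  args <- list(...)
  if (is.null(args$lesion_classes)) {
    args$lesion_classes <- default_lesion_classes(image_size)
  }
  do.call(synthetic_config, c(list(image_size = image_size), args))
}

# Inflate parameter scales so gradients are far from zero (finite-difference
# checks would otherwise drown in roundoff).
inflate_params <- function(model, sd = 0.4, seed = 9L) {
  withr::with_seed(seed, {
    for (pt in fundusformer:::leaf_paths(model)) {
      th <- fundusformer:::get_leaf(model, pt)
      new <- if (is.matrix(th)) {
        matrix(rnorm(length(th), 0, sd), nrow(th), ncol(th))
      } else {
        rnorm(length(th), 0, sd)
      }
      model <- fundusformer:::set_leaf(model, pt, new)
    }
    model
  })
}
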