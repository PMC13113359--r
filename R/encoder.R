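#' Encoder configuration
#'
#' Structural description of the hierarchical transformer encoder: `n_layers`
#' stacked self-attention layers over `n_patches` tokens of width `embed_dim`.
#' Each layer computes, per head, both a neighborhood-restricted attention
#' (softmax normalized only over the Chebyshev-`radius` neighborhood on the
#' patch grid) and a full global attention, and mixes them convexly with a
#' depth-increasing coefficient `alpha(l)`. Token means from the layers listed
#' in `fusion_depths` are fused by softmax-normalized learnable weights into
#' the single global representation.
#'
#' @param n_layers Number of encoder layers L.
#' @param embed_dim Token embedding width E; divisible by `n_heads`.
#' @param n_heads Number of attention heads.
#' @param patch_grid A [patch_grid()] fixing token count and geometry.
#' @param neighborhood_radius Chebyshev radius (in patch-grid steps) of the
#'   local attention neighborhood; constant across layers.
#' @param alpha_mode `"fixed_linear"` (`alpha(l) = l / L`, deterministic),
#'   `"learnable_monotone"` (sigmoid of a base logit plus cumulative positive
#'   increments, learned during training while staying monotone in depth),
#'   or the ablation endpoints `"global_only"` (`alpha = 1` everywhere:
#'   standard global attention, no hierarchical aggregation) and
#'   `"local_only"` (`alpha = 0` everywhere: neighborhood attention only).
#' @param fusion_depths Strictly increasing layer indices whose mean-pooled
#'   token representations are fused; defaults to the last two layers.
#' @param ffn_mult Hidden width of the position-wise feed-forward block, as a
#'   multiple of `embed_dim`.
#' @param stabilized If `TRUE`, apply parameter-free layer normalization
#'   before the attention and feed-forward sub-blocks. The literal update
#'   `t_i^(l) = t_i^(l-1) + FFN(Attn(t_i^(l-1)))` has a single residual and no
#'   normalization; the stabilized variant is an optional deviation used for
#'   training stability and is off by default.
#' @param use_positional If `FALSE`, the positional table is frozen at zero
#'   (the positional-embedding ablation).
#' @return Object of class `encoder_config`.
#' @export
encoder_config <- function(n_layers, embed_dim, n_heads, patch_grid,
                           neighborhood_radius = 1L,
                           alpha_mode = c("fixed_linear", "learnable_monotone",
                                          "global_only", "local_only"),
                           fusion_depths = NULL,
                           ffn_mult = 4L,
                           stabilized = FALSE,
                           use_positional = TRUE) {
  alpha_mode <- match.arg(alpha_mode)
  if (is.null(fusion_depths)) {
    fusion_depths <- unique(c(max(1L, n_layers - 2L), n_layers))
  }
  stopifnot(n_layers >= 1, embed_dim >= 1, n_heads >= 1,
            inherits(patch_grid, "patch_grid"),
            neighborhood_radius >= 0,
            all(diff(fusion_depths) > 0),
            all(fusion_depths >= 1), all(fusion_depths <= n_layers),
            ffn_mult >= 1)
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim must be divisible by n_heads")
  }
  structure(list(
    n_layers = as.integer(n_layers),
    embed_dim = as.integer(embed_dim),
    n_heads = as.integer(n_heads),
    head_dim = as.integer(embed_dim / n_heads),
    patch_grid = patch_grid,
    neighborhood_radius = as.integer(neighborhood_radius),
    alpha_mode = alpha_mode,
    fusion_depths = as.integer(fusion_depths),
    n_levels = length(fusion_depths),
    ffn_mult = as.integer(ffn_mult),
    ffn_dim = as.integer(ffn_mult * embed_dim),
    stabilized = isTRUE(stabilized),
    use_positional = !isFALSE(use_positional)
  ), class = "encoder_config")
}

# Truncated-normal init, truncated at +-2 sd, seeded by caller.
trunc_normal <- function(n, sd = 0.02) {
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

# Fan-in-scaled truncated-normal matrix (sd = 1/sqrt(fan_in)); keeps forward
# activations and backward signal at unit scale regardless of width, so small
# desk-scale models optimize as readily as full-scale ones.
init_matrix <- function(nrow, ncol) {
  matrix(trunc_normal(nrow * ncol, sd = 1 / sqrt(ncol)), nrow, ncol)
}

#' Initialize encoder parameters
#'
#' Projection matrices use a fan-in-scaled truncated normal
#' (sd `1/sqrt(fan_in)`, clipped at two standard deviations); the positional
#' table starts at zero; fusion logits start at zero (uniform level weights).
#' In `learnable_monotone` alpha mode the base logit and increments are
#' initialized so the schedule starts near the linear ramp `l / L`.
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed.
#' @return List of parameter tensors (`patch_projection`, `positional_table`,
#'   `layers`, `fusion_logits`, optionally `alpha_base` / `alpha_incr`).
#' @export
init_encoder_params <- function(config, seed = 1L) {
  E <- config$embed_dim
  N <- config$patch_grid$n_patches
  PD <- config$patch_grid$patch_dim
  Hd <- config$ffn_dim
  with_seed(seed, {
    params <- list(
      patch_projection = init_matrix(E, PD),
      positional_table = matrix(0, N, E),
      layers = lapply(seq_len(config$n_layers), function(l) {
        list(
          Wq = init_matrix(E, E),
          Wk = init_matrix(E, E),
          Wv = init_matrix(E, E),
          Wo = init_matrix(E, E),
          W1 = init_matrix(Hd, E),
          W2 = init_matrix(E, Hd)
        )
      }),
      fusion_logits = rep(0, config$n_levels)
    )
    if (config$alpha_mode == "learnable_monotone") {
      L <- config$n_layers
      target <- stats::qlogis(pmin(pmax(seq_len(L) / L, 0.05), 0.95))
      params$alpha_base <- target[1]
      params$alpha_incr <- if (L > 1) log(pmax(diff(target), 1e-3)) else numeric(0)
    }
    params
  })
}

#' Per-layer local/global mixing schedule
#'
#' Returns `alpha(l)` for every layer: `l / L` in `fixed_linear` mode, or a
#' sigmoid of a base logit plus cumulated positive increments in
#' `learnable_monotone` mode. Both are in \[0, 1\] and non-decreasing with
#' depth.
#'
#' @param config An [encoder_config()].
#' @param params Encoder parameter list (required in learnable mode).
#' @return Numeric vector of length `n_layers`.
#' @export
alpha_schedule <- function(config, params = NULL) {
  L <- config$n_layers
  switch(config$alpha_mode,
    fixed_linear = seq_len(L) / L,
    global_only = rep(1, L),
    local_only = rep(0, L),
    learnable_monotone = {
      stopifnot(!is.null(params$alpha_base))
      logits <- params$alpha_base + c(0, cumsum(exp(params$alpha_incr)))
      plogis(logits)
    })
}

#' Neighborhood of a token on the patch grid
#'
#' All tokens whose Chebyshev (chessboard) distance to token `i` on the 2-D
#' patch grid is at most `radius`, including `i` itself; truncated at the
#' grid border.
#'
#' @param i Token index (1-based, row-major grid order).
#' @param grid A [patch_grid()].
#' @param radius Chebyshev radius >= 0.
#' @return Integer vector of token indices.
#' @export
neighborhood_indices <- function(i, grid, radius) {
  stopifnot(i >= 1, i <= grid$n_patches)
  r0 <- (i - 1) %/% grid$grid_cols + 1
  c0 <- (i - 1) %% grid$grid_cols + 1
  rs <- max(1, r0 - radius):min(grid$grid_rows, r0 + radius)
  cs <- max(1, c0 - radius):min(grid$grid_cols, c0 + radius)
  as.integer(outer(rs - 1, cs, function(r, c) r * grid$grid_cols + c))
}

#' @rdname neighborhood_indices
#' @return `neighborhood_mask` returns the full `n_patches x n_patches`
#'   logical support matrix (row `i` is token `i`'s neighborhood).
#' @export
neighborhood_mask <- function(grid, radius) {
  N <- grid$n_patches
  rows <- (seq_len(N) - 1) %/% grid$grid_cols
  cols <- (seq_len(N) - 1) %% grid$grid_cols
  dr <- abs(outer(rows, rows, "-"))
  dc <- abs(outer(cols, cols, "-"))
  pmax(dr, dc) <= radius
}

#' Embed patch tokens
#'
#' Linear projection of each flattened patch into the embedding space plus
#' its learnable positional embedding: `t_i = W_p z_i + p_i`.
#'
#' @param patches `N x patch_dim` matrix of flattened patches.
#' @param params Encoder parameter list.
#' @return `N x embed_dim` token matrix.
#' @export
embed_tokens <- function(patches, params) {
  if (nrow(patches) != nrow(params$positional_table)) {
    stop("patch count does not match positional table length")
  }
  patches %*% t(params$patch_projection) + params$positional_table
}

#' Scaled dot-product attention rows
#'
#' Computes the row-stochastic attention matrix
#' `a_ij = exp(q_i . k_j / sqrt(d)) / sum_m exp(q_i . k_m / sqrt(d))`,
#' optionally restricting each row's softmax normalization to a logical
#' support mask (neighborhood-restricted attention). Off-support entries are
#' exact zeros.
#'
#' @param queries `N x d` query matrix.
#' @param keys `N x d` key matrix.
#' @param support_mask Optional `N x N` logical support; `NULL` means full.
#' @return `N x N` row-stochastic matrix.
#' @export
attention_rows <- function(queries, keys, support_mask = NULL) {
  d <- ncol(queries)
  stopifnot(d > 0, ncol(keys) == d)
  logits <- tcrossprod(queries, keys) / sqrt(d)
  softmax_rows(logits, support_mask)
}

#' Convex local/global attention mixing
#'
#' `a_mixed = alpha * a_global + (1 - alpha) * a_local`. Because both inputs
#' are row-stochastic and `alpha` lies in \[0, 1\], every mixed row sums to 1
#' by construction — no renormalization is applied.
#'
#' @param a_local,a_global Row-stochastic matrices of identical shape.
#' @param alpha Mixing coefficient in \[0, 1\].
#' @return Row-stochastic matrix of the same shape.
#' @export
mixed_attention <- function(a_local, a_global, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  stopifnot(identical(dim(a_local), dim(a_global)))
  alpha * a_global + (1 - alpha) * a_local
}

# Parameter-free layer normalization over each token (row).
layernorm_rows <- function(x, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  (xc) / sqrt(rowMeans(xc^2) + eps)
}

#' One hierarchical encoder layer
#'
#' Per head: project queries/keys/values, compute the neighborhood-restricted
#' and global attention rows from the same logits, mix them with `alpha`, and
#' aggregate values. Head outputs are concatenated and passed through a
#' learnable merge matrix, followed by the position-wise feed-forward block
#' `W2 gelu(W1 s)`; the layer output is `tokens + ffn` (single residual
#' around the whole block).
#'
#' @param tokens `N x E` input token matrix.
#' @param layer_params List with `Wq`, `Wk`, `Wv`, `Wo`, `W1`, `W2`.
#' @param alpha Mixing coefficient for this layer.
#' @param support_mask `N x N` logical neighborhood support (from
#'   [neighborhood_mask()]).
#' @param n_heads Number of attention heads the projection matrices are split
#'   into.
#' @param stabilized Apply pre-sub-block layer normalization (see
#'   [encoder_config()]).
#' @param keep_attention Retain per-head local/global/mixed attention maps.
#' @return List with `tokens` (`N x E`) and, if requested, `attention` (list
#'   per head of `local`, `global`, `mixed` matrices).
#' @export
encoder_layer <- function(tokens, layer_params, alpha, support_mask,
                          n_heads = 1L, stabilized = FALSE,
                          keep_attention = FALSE) {
  N <- nrow(tokens)
  x <- if (stabilized) layernorm_rows(tokens) else tokens
  q_all <- x %*% t(layer_params$Wq)
  k_all <- x %*% t(layer_params$Wk)
  v_all <- x %*% t(layer_params$Wv)
  E <- ncol(tokens)
  H <- as.integer(n_heads)
  d <- E %/% H
  s_cat <- matrix(0, N, E)
  att <- if (keep_attention) vector("list", H) else NULL
  for (h in seq_len(H)) {
    idx <- ((h - 1) * d + 1):(h * d)
    a_global <- attention_rows(q_all[, idx, drop = FALSE],
                               k_all[, idx, drop = FALSE])
    a_local <- attention_rows(q_all[, idx, drop = FALSE],
                              k_all[, idx, drop = FALSE], support_mask)
    a_mix <- mixed_attention(a_local, a_global, alpha)
    s_cat[, idx] <- a_mix %*% v_all[, idx, drop = FALSE]
    if (keep_attention) {
      att[[h]] <- list(local = a_local, global = a_global, mixed = a_mix)
    }
  }
  s <- s_cat %*% t(layer_params$Wo)
  u <- if (stabilized) layernorm_rows(s) else s
  f <- gelu(u %*% t(layer_params$W1)) %*% t(layer_params$W2)
  list(tokens = tokens + f, attention = att)
}

#' Mean-pool a token sequence
#'
#' Arithmetic mean over tokens: `h^(k) = (1/N) sum_i t_i`.
#'
#' @param tokens `N x E` matrix.
#' @return Length-E vector.
#' @export
pool_level <- function(tokens) {
  stopifnot(nrow(tokens) >= 1)
  colMeans(tokens)
}

#' Fuse multi-depth pooled representations
#'
#' Level weights are obtained by softmax over the fusion logits, so
#' `beta_k >= 0` and `sum_k beta_k = 1` by construction; the fused vector is
#' `h = sum_k beta_k h^(k)`.
#'
#' @param level_pools `K x E` matrix (row k is the depth-k pooled vector) or a
#'   list of K vectors.
#' @param fusion_logits Length-K numeric logits.
#' @return Length-E fused vector with the normalized weights attached as
#'   attribute `"beta"`.
#' @export
fuse_levels <- function(level_pools, fusion_logits) {
  if (is.list(level_pools)) level_pools <- do.call(rbind, level_pools)
  K <- length(fusion_logits)
  stopifnot(K >= 1, nrow(level_pools) == K)
  w <- exp(fusion_logits - max(fusion_logits))
  beta <- w / sum(w)
  fused <- as.numeric(crossprod(level_pools, beta))
  attr(fused, "beta") <- beta
  fused
}

#' Encode an image into its global representation
#'
#' Full forward composition: preprocessing (when given an image),
#' [embed_tokens()], `n_layers` hierarchical encoder layers with the
#' per-layer mixing schedule, mean pooling at the fusion depths, and
#' [fuse_levels()].
#'
#' @param x A `fundus_sample`, an `[H, W, C]` array, or a precomputed
#'   `N x patch_dim` patch matrix.
#' @param stats Channel statistics (ignored when `x` is a patch matrix).
#' @param config An [encoder_config()].
#' @param params Matching parameter list from [init_encoder_params()].
#' @param keep_attention `"none"`, `"final"` or `"all"`: which layers'
#'   attention maps to retain.
#' @return Object of class `global_representation`: list with `fused`
#'   (length E), `beta`, `level_pools` (K x E), `final_tokens` (N x E) and
#'   `attention` (per retained layer, per head).
#' @export
encode <- function(x, config, params, stats = NULL,
                   keep_attention = c("none", "final", "all")) {
  keep_attention <- match.arg(keep_attention)
  grid <- config$patch_grid
  patches <- if (is.matrix(x)) x else {
    stopifnot(!is.null(stats))
    preprocess_image(x, stats, grid)$patches
  }
  tokens <- embed_tokens(patches, params)
  alphas <- alpha_schedule(config, params)
  support <- neighborhood_mask(grid, config$neighborhood_radius)
  pools <- matrix(0, config$n_levels, config$embed_dim)
  attention <- list()
  for (l in seq_len(config$n_layers)) {
    lp <- params$layers[[l]]
    keep <- keep_attention == "all" ||
      (keep_attention == "final" && l == config$n_layers)
    out <- encoder_layer(tokens, lp, alphas[l], support,
                         n_heads = config$n_heads,
                         stabilized = config$stabilized,
                         keep_attention = keep)
    tokens <- out$tokens
    if (keep) attention[[as.character(l)]] <- out$attention
    k <- match(l, config$fusion_depths)
    if (!is.na(k)) pools[k, ] <- pool_level(tokens)
  }
  fused <- fuse_levels(pools, params$fusion_logits)
  structure(list(
    fused = as.numeric(fused),
    beta = attr(fused, "beta"),
    level_pools = pools,
    final_tokens = tokens,
    attention = attention
  ), class = "global_representation")
}
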