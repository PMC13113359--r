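#' Stochastic augmentation configuration
#'
#' Spatial transformations (horizontal/vertical flips, small rotations) and
#' photometric jitter (multiplicative brightness, contrast about the
#' FOV-region mean) applied to training samples; masks are transformed
#' identically and labels are unchanged.
#'
#' @param hflip_prob,vflip_prob Flip probabilities in \[0, 1\].
#' @param rotation_max Maximum absolute rotation in degrees.
#' @param brightness_jitter,contrast_jitter Relative half-ranges of the
#'   multiplicative brightness factor and of the contrast factor.
#' @param enabled Master switch.
#' @return Object of class `augment_config`.
#' @export
augment_config <- function(hflip_prob = 0.5, vflip_prob = 0.5,
                           rotation_max = 15, brightness_jitter = 0.1,
                           contrast_jitter = 0.1, enabled = TRUE) {
  stopifnot(hflip_prob >= 0, hflip_prob <= 1, vflip_prob >= 0, vflip_prob <= 1,
            rotation_max >= 0, brightness_jitter >= 0, contrast_jitter >= 0)
  structure(list(hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 rotation_max = rotation_max,
                 brightness_jitter = brightness_jitter,
                 contrast_jitter = contrast_jitter,
                 enabled = isTRUE(enabled)),
            class = "augment_config")
}

flip_image <- function(img, horizontal) {
  if (length(dim(img)) == 2) {
    if (horizontal) img[, rev(seq_len(ncol(img)))] else img[rev(seq_len(nrow(img))), ]
  } else {
    if (horizontal) img[, rev(seq_len(ncol(img))), , drop = FALSE] else
      img[rev(seq_len(nrow(img))), , , drop = FALSE]
  }
}

rotate_raster <- function(x, angle, binary = FALSE) {
  s <- dim(x)[1:2]
  out <- EBImage::rotate(x, angle, filter = "bilinear",
                         output.dim = s, bg.col = 0)
  out <- as.array(out)
  if (binary) out <- matrix(as.integer(out > 0.5), s[1], s[2])
  out
}

#' Augment one sample
#'
#' Applies, in order: horizontal flip (by probability), vertical flip,
#' rotation uniform in `[-rotation_max, rotation_max]` about the image center
#' (FOV and lesion masks transformed identically), a multiplicative
#' brightness factor, and a contrast adjustment about the FOV-region mean.
#' Deterministic given `seed`.
#'
#' @param sample A `fundus_sample`.
#' @param config An [augment_config()].
#' @param seed Integer seed.
#' @return Augmented `fundus_sample` (labels, severity, group unchanged).
#' @export
augment_sample <- function(sample, config, seed = 1L) {
  stopifnot(inherits(config, "augment_config"))
  if (!config$enabled) return(sample)
  with_seed(seed, {
    img <- sample$image; fov <- sample$fov_mask; les <- sample$lesion_mask
    if (runif(1) < config$hflip_prob) {
      img <- flip_image(img, TRUE); fov <- flip_image(fov, TRUE)
      les <- flip_image(les, TRUE)
    }
    if (runif(1) < config$vflip_prob) {
      img <- flip_image(img, FALSE); fov <- flip_image(fov, FALSE)
      les <- flip_image(les, FALSE)
    }
    if (config$rotation_max > 0) {
      ang <- runif(1, -config$rotation_max, config$rotation_max)
      img <- rotate_raster(img, ang)
      fov <- rotate_raster(fov, ang, binary = TRUE)
      les <- rotate_raster(les, ang, binary = TRUE)
    }
    if (config$brightness_jitter > 0) {
      img <- img * (1 + runif(1, -config$brightness_jitter,
                              config$brightness_jitter))
    }
    if (config$contrast_jitter > 0 && sum(fov) > 0) {
      cf <- 1 + runif(1, -config$contrast_jitter, config$contrast_jitter)
      m <- mean(img[rep(fov == 1, dim(img)[3])])
      adj <- m + (img - m) * cf
      for (c in seq_len(dim(img)[3])) {
        img[, , c] <- ifelse(fov == 1, adj[, , c], img[, , c])
      }
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    out <- sample
    out$image <- img; out$fov_mask <- fov; out$lesion_mask <- les
    out
  })
}

#' Training configuration
#'
#' Mirrors the full-scale training recipe (AdamW, decoupled weight decay
#' 1e-2, exponential learning-rate decay, early stopping on validation loss)
#' at desk scale. `optimizer = "plain_sgd"` switches to the literal
#' gradient-descent update `theta - eta * grad` with no momentum or decay
#' state, useful for verifying the update rule in isolation.
#'
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size; the last partial batch is kept.
#' @param optimizer `"adamw"` or `"plain_sgd"`.
#' @param lr0 Initial learning rate (eta_0 > 0).
#' @param decay Exponential decay factor gamma in (0, 1].
#' @param decay_unit Whether the exponent counts `"epoch"`s or `"step"`s.
#' @param weight_decay Decoupled weight-decay rate (AdamW only; applied to
#'   projection matrices, not to positional embeddings or fusion/alpha
#'   logits).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping; the best-epoch snapshot is returned.
#' @param seed Master seed for shuffling and augmentation.
#' @param augmentation An [augment_config()]; disabled by default because the
#'   synthetic generator already randomizes illumination and geometry.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 16L,
                         optimizer = c("adamw", "plain_sgd"),
                         lr0 = 1e-3, decay = 0.97,
                         decay_unit = c("epoch", "step"),
                         weight_decay = 1e-2, early_stop_patience = 10L,
                         seed = 1L,
                         augmentation = augment_config(enabled = FALSE)) {
  optimizer <- match.arg(optimizer)
  decay_unit <- match.arg(decay_unit)
  stopifnot(lr0 >= 0,
            decay > 0, decay <= 1, epochs >= 1, batch_size >= 1,
            weight_decay >= 0, early_stop_patience >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 optimizer = optimizer, lr0 = lr0, decay = decay,
                 decay_unit = decay_unit, weight_decay = weight_decay,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), augmentation = augmentation),
            class = "train_config")
}

#' Exponentially decayed learning rate
#'
#' `eta_t = eta_0 * gamma^t`, with `t` counting steps or epochs according to
#' the configuration's `decay_unit`.
#'
#' @param t Iteration index (>= 0).
#' @param config A [train_config()] (or any list with `lr0` and `decay`).
#' @return Learning rate at iteration `t`.
#' @export
lr_at <- function(t, config) {
  stopifnot(all(t >= 0))
  config$lr0 * config$decay^t
}

# ---- parameter-tree plumbing -------------------------------------------------

# Flat enumeration of every trainable tensor: list of c(where, ...) paths.
leaf_paths <- function(model) {
  paths <- list(c("params", "patch_projection"))
  if (model$config$use_positional %||% TRUE) {
    paths[[length(paths) + 1]] <- c("params", "positional_table")
  }
  for (l in seq_len(model$config$n_layers)) {
    for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2")) {
      paths[[length(paths) + 1]] <- c("params", "layers", l, nm)
    }
  }
  paths[[length(paths) + 1]] <- c("params", "fusion_logits")
  if (model$config$alpha_mode == "learnable_monotone") {
    paths[[length(paths) + 1]] <- c("params", "alpha_base")
    if (model$config$n_layers > 1) {
      paths[[length(paths) + 1]] <- c("params", "alpha_incr")
    }
  }
  paths[[length(paths) + 1]] <- c("head", "screening_projection")
  paths[[length(paths) + 1]] <- c("head", "class_weights")
  paths
}

get_leaf <- function(model, path) {
  x <- model
  for (p in path) x <- x[[if (grepl("^[0-9]+$", p)) as.integer(p) else p]]
  x
}

set_leaf <- function(model, path, value) {
  key <- function(p) if (grepl("^[0-9]+$", p)) as.integer(p) else p
  if (length(path) == 1) { model[[key(path)]] <- value; return(model) }
  model[[key(path[1])]] <- set_leaf(model[[key(path[1])]], path[-1], value)
  model
}

grad_leaf <- function(grads, path) {
  # grads come keyed without the params/head prefix
  if (path[1] == "head") return(grads[[path[2]]])
  x <- grads
  for (p in path[-1]) x <- x[[if (grepl("^[0-9]+$", p)) as.integer(p) else p]]
  x
}

# Weight decay is applied only to projection matrices.
decayed_leaf <- function(path) {
  nm <- path[length(path)]
  nm %in% c("patch_projection", "Wq", "Wk", "Wv", "Wo", "W1", "W2",
            "screening_projection", "class_weights")
}

# Map the encoder's per-layer alpha gradient onto the learnable-schedule
# parameters (sigmoid of base logit + cumulated exp increments).
alpha_param_grads <- function(model, dalpha) {
  L <- model$config$n_layers
  logits <- model$params$alpha_base +
    c(0, cumsum(exp(model$params$alpha_incr)))
  a <- plogis(logits)
  dlogit <- dalpha * a * (1 - a)
  out <- list(alpha_base = sum(dlogit))
  if (L > 1) {
    tail_sums <- rev(cumsum(rev(dlogit)))[-1]  # sum over l >= j + 1
    out$alpha_incr <- exp(model$params$alpha_incr) * tail_sums
  }
  out
}

#' One optimizer step
#'
#' Applies either the plain gradient-descent rule
#' `theta <- theta - eta * grad` or a decoupled-weight-decay AdamW update
#' (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) to every trainable tensor.
#'
#' @param model A `fundus_model`.
#' @param grads Gradient structure as produced by the training loop.
#' @param lr Learning rate for this step.
#' @param config A [train_config()].
#' @param state Optimizer state (moment estimates), or `NULL` on first call.
#' @return List with updated `model` and `state`.
#' @export
optimizer_step <- function(model, grads, lr, config, state = NULL) {
  paths <- leaf_paths(model)
  if (is.null(state)) {
    state <- list(t = 0L, m = vector("list", length(paths)),
                  v = vector("list", length(paths)))
  }
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (i in seq_along(paths)) {
    path <- paths[[i]]
    theta <- get_leaf(model, path)
    g <- grad_leaf(grads, path)
    if (is.null(dim(theta))) g <- as.numeric(g)  # arma vectors wrap as n x 1
    if (config$optimizer == "plain_sgd") {
      theta <- theta - lr * g
    } else {
      if (is.null(state$m[[i]])) {
        state$m[[i]] <- theta * 0; state$v[[i]] <- theta * 0
      }
      state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
      state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g^2
      mhat <- state$m[[i]] / (1 - b1^state$t)
      vhat <- state$v[[i]] / (1 - b2^state$t)
      wd <- if (decayed_leaf(path)) config$weight_decay else 0
      theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + wd * theta)
    }
    model <- set_leaf(model, path, theta)
  }
  list(model = model, state = state)
}

sum_grad_trees <- function(a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- sum_grad_trees(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}

scale_grad_tree <- function(a, s) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- scale_grad_tree(a[[nm]], s)
    a
  } else {
    a * s
  }
}

# Forward-only mean loss over precomputed patch matrices.
mean_loss <- function(model, patch_list, labels) {
  cfg <- model$config
  alphas <- alpha_schedule(cfg, model$params)
  nb <- support_mask_int(cfg)
  total <- 0
  for (i in seq_along(patch_list)) {
    fwd <- encoder_forward_cpp(patch_list[[i]], model$params, alphas, nb,
                               cfg$fusion_depths, cfg$n_heads, cfg$stabilized)
    r <- project_screening(as.numeric(fwd$fused), model$head)
    p <- sigmoid(as.numeric(model$head$class_weights %*% r))
    total <- total + loss_multi(labels[i, ], p)
  }
  total / length(patch_list)
}

#' Train a screening model
#'
#' Minimizes the mean summed binary cross-entropy over mini-batches with the
#' configured optimizer and exponential learning-rate schedule, evaluating
#' the validation loss each epoch and stopping early when it fails to improve
#' for `early_stop_patience` epochs. The returned model is the best-epoch
#' snapshot. All randomness (shuffling, augmentation) derives from
#' `config$seed`.
#'
#' @param model A [fundus_model()].
#' @param dataset A `fundus_dataset` (train + validation partitions used).
#' @param config A [train_config()].
#' @param stats Optional precomputed channel statistics; fit on the training
#'   partition when `NULL`.
#' @param verbose Print per-epoch progress.
#' @return Object of class `fundus_fit`: list with `model`, `history`
#'   (data.frame epoch/train_loss/val_loss/lr), `stats`, `thresholds`
#'   (validation-selected per-class thresholds), `best_epoch`.
#' @export
train_model <- function(model, dataset, config = train_config(),
                        stats = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "fundus_model"), inherits(config, "train_config"))
  train_set <- dataset$train
  val_set <- dataset$validation
  if (length(train_set) == 0) stop("dataset has no training partition")
  if (is.null(stats)) stats <- fit_channel_stats(train_set)
  cfg <- model$config
  grid <- cfg$patch_grid
  nb <- support_mask_int(cfg)

  set_flush_denormals(TRUE)  # subnormal arithmetic cripples CPU throughput
  on.exit(set_flush_denormals(FALSE), add = TRUE)

  prep <- function(s) preprocess_image(s, stats, grid)$patches
  train_patches <- lapply(train_set, prep)
  val_patches <- lapply(val_set, prep)
  y_train <- dataset_labels(train_set)
  y_val <- if (length(val_set)) dataset_labels(val_set) else NULL
  n <- length(train_set)
  aug <- config$augmentation$enabled

  best <- list(val = Inf, model = model, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  state <- NULL
  step <- 0L
  stall <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 7000000L + epoch), sample(n))
    epoch_loss <- 0
    batch_starts <- seq(1, n, by = config$batch_size)
    for (bi in seq_along(batch_starts)) {
      ids <- ord[batch_starts[bi]:min(batch_starts[bi] + config$batch_size - 1, n)]
      alphas <- alpha_schedule(cfg, model$params)
      acc <- NULL
      acc_alpha <- numeric(cfg$n_layers)
      batch_loss <- 0
      for (i in ids) {
        Zp <- if (aug) {
          s_aug <- augment_sample(train_set[[i]], config$augmentation,
                                  seed = derive_seed(config$seed,
                                                     epoch * 100000L + i))
          prep(s_aug)
        } else {
          train_patches[[i]]
        }
        out <- model_grad_cpp(Zp, model$params, model$head, y_train[i, ],
                              alphas, nb, cfg$fusion_depths, cfg$n_heads,
                              cfg$stabilized)
        if (!is.finite(out$loss)) {
          stop("non-finite loss in epoch ", epoch, ", batch ", bi,
               " (sample ", i, ")")
        }
        batch_loss <- batch_loss + out$loss
        g <- out$grads
        acc_alpha <- acc_alpha + as.numeric(g$alpha)
        g$alpha <- NULL
        acc <- if (is.null(acc)) g else sum_grad_trees(acc, g)
      }
      bs <- length(ids)
      acc <- scale_grad_tree(acc, 1 / bs)
      if (cfg$alpha_mode == "learnable_monotone") {
        ag <- alpha_param_grads(model, acc_alpha / bs)
        acc$alpha_base <- ag$alpha_base
        if (!is.null(ag$alpha_incr)) acc$alpha_incr <- ag$alpha_incr
      }
      t_idx <- if (config$decay_unit == "step") step else epoch - 1L
      lr <- lr_at(t_idx, config)
      upd <- optimizer_step(model, acc, lr, config, state)
      model <- upd$model; state <- upd$state
      step <- step + 1L
      epoch_loss <- epoch_loss + batch_loss
    }
    model$step <- step
    train_loss <- epoch_loss / n
    val_loss <- if (length(val_patches)) {
      mean_loss(model, val_patches, y_val)
    } else {
      train_loss
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss,
      lr = lr_at(if (config$decay_unit == "step") step - 1L else epoch - 1L,
                 config)))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      train_loss, val_loss))
    }
    if (val_loss < best$val - 1e-12) {
      best <- list(val = val_loss, model = model, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stop_patience) break
    }
  }

  thresholds <- NULL
  if (length(val_set)) {
    vp <- predict_dataset(best$model, val_set, stats)$probabilities
    ok <- vapply(seq_len(ncol(vp)), function(c) {
      length(unique(y_val[, c])) == 2
    }, logical(1))
    thresholds <- rep(0.5, ncol(vp))
    if (any(ok)) {
      thresholds[ok] <- select_thresholds(vp[, ok, drop = FALSE],
                                          y_val[, ok, drop = FALSE])
    }
  }
  structure(list(model = best$model, history = history, stats = stats,
                 thresholds = thresholds, best_epoch = best$epoch,
                 train_config = config),
            class = "fundus_fit")
}
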