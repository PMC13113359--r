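#' Construct a screening model
#'
#' Bundles an encoder configuration with freshly initialized encoder and head
#' parameters into a single trainable object.
#'
#' @param config An [encoder_config()].
#' @param n_classes Number of disease classes C (1 for single-disease).
#' @param screen_dim Screening-space dimension D; defaults to
#'   `min(256, embed_dim)`.
#' @param seed Integer seed for parameter initialization.
#' @return Object of class `fundus_model`.
#' @export
fundus_model <- function(config, n_classes, screen_dim = NULL, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"), n_classes >= 1)
  if (is.null(screen_dim)) screen_dim <- min(256L, config$embed_dim)
  structure(list(
    config = config,
    n_classes = as.integer(n_classes),
    screen_dim = as.integer(screen_dim),
    params = init_encoder_params(config, seed = derive_seed(seed, 1L)),
    head = init_head_params(config$embed_dim, n_classes, screen_dim,
                            seed = derive_seed(seed, 2L)),
    step = 0L,
    seed = as.integer(seed)
  ), class = "fundus_model")
}

#' @export
print.fundus_model <- function(x, ...) {
  cfg <- x$config
  cat("fundus_model: L =", cfg$n_layers, "| E =", cfg$embed_dim,
      "| heads =", cfg$n_heads, "| N =", cfg$patch_grid$n_patches,
      "| classes =", x$n_classes, "| step =", x$step, "\n")
  invisible(x)
}

# Integer support mask for the compiled path.
support_mask_int <- function(config) {
  m <- neighborhood_mask(config$patch_grid, config$neighborhood_radius)
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Model forward pass
#'
#' Encodes patches (or a sample/image) and applies the screening head. The
#' default uses the compiled fast path; set `keep_attention` to retain the
#' final-layer attention maps via the R reference path (needed for
#' interpretability analyses).
#'
#' @param model A [fundus_model()].
#' @param x Patch matrix, `fundus_sample`, or image array.
#' @param stats Channel statistics (required unless `x` is a patch matrix).
#' @param thresholds Optional per-class decision thresholds.
#' @param keep_attention `"none"` (fast path) or `"final"`/`"all"`.
#' @return A `screening_prediction` with the `global_representation` attached
#'   as attribute `"representation"`.
#' @export
model_forward <- function(model, x, stats = NULL, thresholds = NULL,
                          keep_attention = "none") {
  cfg <- model$config
  patches <- if (is.matrix(x)) x else {
    preprocess_image(x, stats, cfg$patch_grid)$patches
  }
  if (keep_attention == "none") {
    fwd <- encoder_forward_cpp(patches, model$params,
                               alpha_schedule(cfg, model$params),
                               support_mask_int(cfg),
                               cfg$fusion_depths, cfg$n_heads,
                               cfg$stabilized)
    rep <- structure(list(fused = as.numeric(fwd$fused),
                          beta = as.numeric(fwd$beta),
                          level_pools = fwd$level_pools,
                          final_tokens = fwd$final_tokens,
                          attention = list()),
                     class = "global_representation")
  } else {
    rep <- encode(patches, cfg, model$params, stats = stats,
                  keep_attention = keep_attention)
  }
  r <- project_screening(rep$fused, model$head)
  pred <- predict_screening(r, model$head, thresholds)
  attr(pred, "representation") <- rep
  pred
}

#' Predict screening probabilities for a set of samples
#'
#' @param model A [fundus_model()].
#' @param samples List of `fundus_sample` objects (or patch matrices).
#' @param stats Channel statistics.
#' @param thresholds Optional per-class thresholds.
#' @return List with `probabilities` and `decisions` (`n x C` matrices).
#' @export
predict_dataset <- function(model, samples, stats, thresholds = NULL) {
  C <- model$n_classes
  probs <- matrix(0, length(samples), C)
  for (i in seq_along(samples)) {
    probs[i, ] <- model_forward(model, samples[[i]], stats)$probabilities
  }
  thr <- thresholds %||% rep(0.5, C)
  list(probabilities = probs,
       decisions = matrix(as.integer(t(t(probs) >= thr)), nrow(probs), C),
       thresholds = thr)
}

CHECKPOINT_VERSION <- 1L

#' Save / load model checkpoints
#'
#' A checkpoint stores the format version, the full configuration, every
#' parameter tensor, the training step and seed. Loading verifies the version
#' field and fails on truncated or incompatible files; [load_checkpoint()]
#' with `expect_config` additionally enforces that the stored configuration
#' matches (e.g. to reject a checkpoint trained at a different patch size).
#'
#' @param model A `fundus_model`.
#' @param path File path.
#' @param stats Optional `channel_stats` to store alongside the model.
#' @param thresholds Optional validation-selected decision thresholds.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `model`, `stats` and `thresholds`.
#' @export
save_checkpoint <- function(model, path, stats = NULL, thresholds = NULL) {
  saveRDS(list(version = CHECKPOINT_VERSION, model = model, stats = stats,
               thresholds = thresholds,
               package_version = as.character(packageVersion("fundusformer"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_config Optional `encoder_config` that the checkpoint must
#'   match exactly.
#' @export
load_checkpoint <- function(path, expect_config = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("checkpoint file is unreadable or truncated: ", conditionMessage(e))
  })
  if (!is.list(obj) || is.null(obj$version)) {
    stop("not a fundusformer checkpoint: missing version field")
  }
  if (obj$version != CHECKPOINT_VERSION) {
    stop("incompatible checkpoint version ", obj$version,
         " (expected ", CHECKPOINT_VERSION, ")")
  }
  if (!is.null(expect_config) &&
      !isTRUE(all.equal(obj$model$config, expect_config))) {
    stop("checkpoint/config mismatch: the stored encoder configuration ",
         "differs from the requested one")
  }
  list(model = obj$model, stats = obj$stats, thresholds = obj$thresholds)
}
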