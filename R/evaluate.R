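#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney) formulation with half credit for ties: the
#' probability that a random positive scores above a random negative.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive).
#' @return AUROC in \[0, 1\], or `NA` if only one class is present.
#' @export
auroc <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Screening metrics from decisions, scores and labels
#'
#' Per class: confusion counts, accuracy, sensitivity `tp / (tp + fn)`,
#' specificity `tn / (tn + fp)`, F1 `2 tp / (2 tp + fp + fn)`, and AUROC.
#' Macro aggregates are unweighted class means; a class with a single label
#' value has undefined AUROC and is excluded from the macro AUROC with a
#' warning.
#'
#' @param decisions `n x C` binary decision matrix (or vector).
#' @param probabilities `n x C` score matrix (or vector).
#' @param labels `n x C` binary label matrix (or vector).
#' @return Object of class `metrics_report`: list with `accuracy`,
#'   `macro_f1`, `sensitivity`, `specificity`, `auroc` and a `per_class`
#'   data frame.
#' @export
compute_metrics <- function(decisions, probabilities, labels) {
  d <- as.matrix(decisions); p <- as.matrix(probabilities)
  y <- as.matrix(labels)
  stopifnot(identical(dim(d), dim(y)), identical(dim(p), dim(y)))
  C <- ncol(y)
  per <- lapply(seq_len(C), function(c) {
    tp <- sum(d[, c] == 1 & y[, c] == 1)
    fp <- sum(d[, c] == 1 & y[, c] == 0)
    tn <- sum(d[, c] == 0 & y[, c] == 0)
    fn <- sum(d[, c] == 0 & y[, c] == 1)
    a <- auroc(p[, c], y[, c])
    data.frame(
      class = c, tp = tp, fp = fp, tn = tn, fn = fn,
      accuracy = (tp + tn) / length(y[, c]),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
      auroc = a)
  })
  per <- do.call(rbind, per)
  if (anyNA(per$auroc)) {
    warning("AUROC undefined for ", sum(is.na(per$auroc)),
            " class(es) with a single label value; excluded from macro AUROC")
  }
  structure(list(
    accuracy = mean(per$accuracy),
    macro_f1 = mean(per$f1, na.rm = TRUE),
    sensitivity = mean(per$sensitivity, na.rm = TRUE),
    specificity = mean(per$specificity, na.rm = TRUE),
    auroc = if (all(is.na(per$auroc))) NA_real_ else mean(per$auroc, na.rm = TRUE),
    per_class = per
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics: accuracy %.3f | macro-F1 %.3f | sens %.3f | spec %.3f | AUROC %s\n",
    x$accuracy, x$macro_f1, x$sensitivity, x$specificity,
    ifelse(is.na(x$auroc), "NA", sprintf("%.3f", x$auroc))))
  invisible(x)
}

#' Degradation specification
#'
#' @param kind One of `"brightness_down"`, `"brightness_up"`,
#'   `"contrast_down"`, `"gaussian_blur"`, `"gaussian_noise"`.
#' @param levels Severity values, strictly increasing.
#' @param seed Seed for stochastic kinds (noise).
#' @return Object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind, levels, seed = 1L) {
  kind <- match.arg(kind, c("brightness_down", "brightness_up",
                            "contrast_down", "gaussian_blur",
                            "gaussian_noise"))
  stopifnot(length(levels) >= 1, all(diff(levels) > 0) || length(levels) == 1,
            all(levels >= 0))
  structure(list(kind = kind, levels = levels, seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Apply one image degradation
#'
#' Brightness changes multiply intensities inside the FOV by `1 -/+ level`;
#' contrast reduction blends FOV pixels toward the FOV-region mean by factor
#' `level`; blur applies an isotropic Gaussian kernel with `sd = level`
#' pixels; noise adds zero-mean Gaussian noise with `sd = level`. The result
#' is clipped to \[0, 1\] and the FOV mask is unchanged. `level = 0` is the
#' identity for every kind.
#'
#' @param image `[H, W, C]` array in \[0, 1\].
#' @param spec A [perturbation_spec()].
#' @param level_index Which of the spec's levels to apply.
#' @param fov_mask Binary FOV mask.
#' @param seed Seed for the noise draw; defaults to the spec's seed.
#' @return Degraded image array.
#' @export
perturb_image <- function(image, spec, level_index, fov_mask,
                          seed = spec$seed) {
  stopifnot(inherits(spec, "perturbation_spec"),
            level_index >= 1, level_index <= length(spec$levels))
  level <- spec$levels[level_index]
  if (level == 0) return(image)
  img <- as_image_array(image)
  fov <- as.matrix(fov_mask)
  out <- img
  if (spec$kind %in% c("brightness_down", "brightness_up")) {
    f <- if (spec$kind == "brightness_down") 1 - level else 1 + level
    for (c in seq_len(dim(img)[3])) {
      out[, , c] <- ifelse(fov == 1, img[, , c] * f, img[, , c])
    }
  } else if (spec$kind == "contrast_down") {
    m <- mean(img[rep(fov == 1, dim(img)[3])])
    for (c in seq_len(dim(img)[3])) {
      out[, , c] <- ifelse(fov == 1, (1 - level) * img[, , c] + level * m,
                           img[, , c])
    }
  } else if (spec$kind == "gaussian_blur") {
    out <- as.array(EBImage::gblur(img, sigma = level))
  } else if (spec$kind == "gaussian_noise") {
    out <- with_seed(seed, img + array(rnorm(length(img), 0, level),
                                       dim = dim(img)))
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Evaluate a model on a sample set
#'
#' @param model A `fundus_model`.
#' @param samples List of `fundus_sample` objects.
#' @param stats Channel statistics.
#' @param thresholds Per-class decision thresholds (default 0.5).
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, samples, stats, thresholds = NULL) {
  pred <- predict_dataset(model, samples, stats, thresholds)
  compute_metrics(pred$decisions, pred$probabilities, dataset_labels(samples))
}

#' Degradation-robustness suite
#'
#' Evaluates the model on clean test images and on every degradation level
#' of every spec, and summarizes (per spec) the performance drop — the clean
#' metric minus the mean degraded metric, in percentage points — for
#' accuracy, macro-F1 and AUROC. The stability index is the fraction of test
#' samples whose thresholded per-class decisions are identical to their
#' clean-image decisions at every degradation level of the whole suite,
#' reported as a percentage.
#'
#' @param model A `fundus_model`.
#' @param test_set List of `fundus_sample` objects.
#' @param specs List of [perturbation_spec()]s.
#' @param stats Channel statistics.
#' @param thresholds Per-class decision thresholds.
#' @return List with `clean` (metrics_report), `per_spec` data frame
#'   (kind, level, accuracy, macro_f1, auroc), `drops` data frame and
#'   `stability_index` (percent).
#' @export
robustness_suite <- function(model, test_set, specs, stats,
                             thresholds = NULL) {
  labels <- dataset_labels(test_set)
  clean_pred <- predict_dataset(model, test_set, stats, thresholds)
  clean <- compute_metrics(clean_pred$decisions, clean_pred$probabilities,
                           labels)
  stable <- rep(TRUE, length(test_set))
  rows <- list(); drops <- list()
  for (spec in specs) {
    accs <- f1s <- aucs <- numeric(length(spec$levels))
    for (li in seq_along(spec$levels)) {
      probs <- matrix(0, length(test_set), model$n_classes)
      for (i in seq_along(test_set)) {
        s <- test_set[[i]]
        deg <- perturb_image(s$image, spec, li, s$fov_mask,
                             seed = derive_seed(spec$seed, i))
        probs[i, ] <- model_forward(model,
          preprocess_image(deg, stats, model$config$patch_grid,
                           fov_mask = s$fov_mask)$patches)$probabilities
      }
      thr <- thresholds %||% rep(0.5, model$n_classes)
      dec <- matrix(as.integer(t(t(probs) >= thr)), nrow(probs))
      stable <- stable & rowSums(dec != clean_pred$decisions) == 0
      m <- compute_metrics(dec, probs, labels)
      accs[li] <- m$accuracy; f1s[li] <- m$macro_f1; aucs[li] <- m$auroc
      rows[[length(rows) + 1]] <- data.frame(
        kind = spec$kind, level = spec$levels[li],
        accuracy = m$accuracy, macro_f1 = m$macro_f1, auroc = m$auroc)
    }
    drops[[length(drops) + 1]] <- data.frame(
      kind = spec$kind,
      accuracy_drop = 100 * (clean$accuracy - mean(accs)),
      macro_f1_drop = 100 * (clean$macro_f1 - mean(f1s)),
      auroc_drop = 100 * (clean$auroc - mean(aucs)))
  }
  list(clean = clean,
       per_spec = do.call(rbind, rows),
       drops = do.call(rbind, drops),
       stability_index = 100 * mean(stable))
}

patch_categories <- function(lesion_mask, fov_mask, grid) {
  les <- resize_image(as.matrix(lesion_mask), grid$target_size, binary = TRUE)
  fov <- resize_image(as.matrix(fov_mask), grid$target_size, binary = TRUE)
  P <- grid$patch_size
  N <- grid$n_patches
  lesion_patch <- logical(N); outside_patch <- logical(N)
  for (gr in seq_len(grid$grid_rows)) {
    rows <- ((gr - 1) * P + 1):(gr * P)
    for (gc in seq_len(grid$grid_cols)) {
      cols <- ((gc - 1) * P + 1):(gc * P)
      i <- (gr - 1) * grid$grid_cols + gc
      lesion_patch[i] <- any(les[rows, cols] == 1)
      outside_patch[i] <- all(fov[rows, cols] == 0)
    }
  }
  list(lesion = lesion_patch, outside = outside_patch,
       any_lesion = any(les == 1))
}

saliency_fractions <- function(sal, lesion_mask, fov_mask, grid) {
  cats <- patch_categories(lesion_mask, fov_mask, grid)
  if (!cats$any_lesion) {
    return(list(relevant_region_coverage = NA_real_,
                diffuse_attention = NA_real_, misaligned_focus = NA_real_,
                saliency = sal, lesion_patch_fraction = 0))
  }
  cov <- sum(sal[cats$lesion])
  mis <- sum(sal[cats$outside & !cats$lesion])
  list(relevant_region_coverage = cov,
       diffuse_attention = 1 - cov - mis,
       misaligned_focus = mis,
       saliency = sal,
       lesion_patch_fraction = mean(cats$lesion))
}

layer_saliency <- function(attention_layer) {
  heads <- if (!is.null(attention_layer$mixed)) list(attention_layer) else
    attention_layer
  Reduce(`+`, lapply(heads, function(h) colMeans(h$mixed))) / length(heads)
}

#' Attention alignment with lesion ground truth
#'
#' Builds a patch-level saliency from one encoder layer's attention by
#' averaging, across heads, the attention each token receives (column means
#' of the mixed attention matrices); since rows are stochastic the saliency
#' sums to one over patches. The saliency mass is then partitioned into:
#' coverage of patches overlapping the lesion mask, misaligned focus on
#' patches entirely outside the FOV, and diffuse attention (the remainder).
#'
#' @param attention One layer's attention: list per head with a `mixed`
#'   matrix (as retained by [encode()]).
#' @param lesion_mask Binary lesion mask at the grid's target resolution (or
#'   resizable to it).
#' @param fov_mask Binary FOV mask, same convention.
#' @param grid A [patch_grid()].
#' @return List with `relevant_region_coverage`, `diffuse_attention`,
#'   `misaligned_focus`, `saliency` (length-N vector), and
#'   `lesion_patch_fraction` (the uniform-attention baseline). `NA` fractions
#'   if the sample has no lesion pixels.
#' @export
attention_alignment <- function(attention, lesion_mask, fov_mask, grid) {
  saliency_fractions(layer_saliency(attention), lesion_mask, fov_mask, grid)
}

#' Fusion-weighted model saliency for one sample
#'
#' Patch-level saliency aggregated over the fusion depths: at each retained
#' depth the attention received by every token (head-averaged column means of
#' the mixed attention) is computed, and the per-depth saliencies are
#' combined with the learned fusion weights `beta` — the same weights that
#' combine those depths into the global representation. Sums to one over
#' patches.
#'
#' @param model A `fundus_model`.
#' @param sample A `fundus_sample` (or image array with `fov_mask` given).
#' @param stats Channel statistics.
#' @return List with the alignment fractions (as in [attention_alignment()])
#'   and the saliency vector.
#' @export
model_saliency <- function(model, sample, stats) {
  pred <- model_forward(model, sample, stats, keep_attention = "all")
  rep <- attr(pred, "representation")
  depths <- model$config$fusion_depths
  sal <- 0
  for (k in seq_along(depths)) {
    sal <- sal + rep$beta[k] * layer_saliency(rep$attention[[as.character(depths[k])]])
  }
  saliency_fractions(sal, sample$lesion_mask, sample$fov_mask,
                     model$config$patch_grid)
}

#' Attention alignment over a sample set
#'
#' Computes the fusion-weighted saliency ([model_saliency()]) for each
#' lesion-positive sample and averages the alignment fractions; samples
#' without lesions are excluded with a count.
#'
#' @param model A `fundus_model`.
#' @param samples List of `fundus_sample` objects.
#' @param stats Channel statistics.
#' @return List with mean `relevant_region_coverage`, `diffuse_attention`,
#'   `misaligned_focus`, mean `lesion_patch_fraction` baseline, `n_used`,
#'   `n_excluded`, and the per-sample data frame.
#' @export
alignment_suite <- function(model, samples, stats) {
  rows <- list(); n_excl <- 0L
  for (s in samples) {
    if (!any(s$lesion_mask == 1)) { n_excl <- n_excl + 1L; next }
    al <- model_saliency(model, s, stats)
    rows[[length(rows) + 1]] <- data.frame(
      coverage = al$relevant_region_coverage,
      diffuse = al$diffuse_attention,
      misaligned = al$misaligned_focus,
      baseline = al$lesion_patch_fraction)
  }
  per <- do.call(rbind, rows)
  list(relevant_region_coverage = mean(per$coverage),
       diffuse_attention = mean(per$diffuse),
       misaligned_focus = mean(per$misaligned),
       lesion_patch_fraction = mean(per$baseline),
       n_used = nrow(per), n_excluded = n_excl, per_sample = per)
}

#' Cross-domain performance retention
#'
#' `100 * cross_domain / in_domain`, passed through without capping.
#'
#' @param in_domain_metric In-domain metric value (> 0).
#' @param cross_domain_metric Cross-domain metric value.
#' @return Retention percentage.
#' @export
retention <- function(in_domain_metric, cross_domain_metric) {
  if (in_domain_metric == 0) stop("in-domain metric is zero")
  100 * cross_domain_metric / in_domain_metric
}
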