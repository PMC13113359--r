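#' Patch-grid geometry
#'
#' Fixes the tokenization geometry: images are resized to
#' `target_size x target_size` and cut into non-overlapping
#' `patch_size x patch_size` squares, flattened row-major over the grid
#' (top-left origin, rows before columns) into vectors of length
#' `patch_size^2 * n_channels`.
#'
#' @param target_size Side length H = W in pixels after resizing.
#' @param patch_size Patch side length P; must divide `target_size`.
#' @param n_channels Number of image channels.
#' @return Object of class `patch_grid` with fields `target_size`,
#'   `patch_size`, `grid_rows`, `grid_cols`, `n_patches`, `patch_dim`.
#' @export
patch_grid <- function(target_size, patch_size, n_channels = 3L) {
  stopifnot(target_size >= patch_size, patch_size >= 1)
  if (target_size %% patch_size != 0) {
    stop("target_size (", target_size, ") is not divisible by patch_size (",
         patch_size, ")")
  }
  g <- as.integer(target_size / patch_size)
  structure(list(
    target_size = as.integer(target_size),
    patch_size = as.integer(patch_size),
    grid_rows = g, grid_cols = g,
    n_patches = g * g,
    patch_dim = as.integer(patch_size^2 * n_channels),
    n_channels = as.integer(n_channels)
  ), class = "patch_grid")
}

#' Pooled per-channel moments of a training set
#'
#' Computes, for each color channel, the mean and (population) standard
#' deviation pooled over every pixel of every training image. These statistics
#' are fit on the training partition only and reused verbatim for validation
#' and test images.
#'
#' @param images List of `[H, W, C]` arrays, or `fundus_sample` objects.
#' @return Object of class `channel_stats` with `means`, `sds`, `n_images`.
#' @export
fit_channel_stats <- function(images) {
  images <- lapply(images, as_image_array)
  stopifnot(length(images) >= 1)
  nc <- dim(images[[1]])[3]
  if (!all(vapply(images, function(im) dim(im)[3], 0L) == nc)) {
    stop("all images must share the same channel count")
  }
  sums <- numeric(nc); sqs <- numeric(nc); npix <- 0
  for (im in images) {
    npix <- npix + prod(dim(im)[1:2])
    for (c in seq_len(nc)) {
      sums[c] <- sums[c] + sum(im[, , c])
      sqs[c] <- sqs[c] + sum(im[, , c]^2)
    }
  }
  means <- sums / npix
  vars <- sqs / npix - means^2
  vars[vars < 0] <- 0
  if (any(vars == 0)) {
    stop("zero variance in channel ", which(vars == 0)[1])
  }
  structure(list(means = means, sds = sqrt(vars), n_images = length(images)),
            class = "channel_stats")
}

as_image_array <- function(x) {
  if (inherits(x, "fundus_sample")) x$image else x
}

#' Channel-wise normalization
#'
#' Standardizes each channel by the training-set moments:
#' `(I(x, y, c) - mean_c) / sd_c`. Spatial resolution is unchanged; the map is
#' affine and exactly invertible via [denormalize_channels()].
#'
#' @param image `[H, W, C]` array.
#' @param stats A [fit_channel_stats()] result.
#' @return Normalized array of the same shape.
#' @export
normalize_channels <- function(image, stats) {
  image <- as_image_array(image)
  nc <- dim(image)[3]
  if (nc != length(stats$means)) {
    stop("image channel count does not match stats")
  }
  out <- image
  for (c in seq_len(nc)) {
    out[, , c] <- (image[, , c] - stats$means[c]) / stats$sds[c]
  }
  out
}

#' @rdname normalize_channels
#' @export
denormalize_channels <- function(image, stats) {
  out <- image
  for (c in seq_len(dim(image)[3])) {
    out[, , c] <- image[, , c] * stats$sds[c] + stats$means[c]
  }
  out
}

#' Apply a field-of-view mask
#'
#' Element-wise multiplication of the (normalized) image with a binary mask,
#' broadcast over channels: every pixel outside the FOV becomes exactly 0.
#' Idempotent.
#'
#' @param image `[H, W, C]` array.
#' @param mask `[H, W]` binary (0/1) matrix.
#' @return Masked array.
#' @export
apply_fov_mask <- function(image, mask) {
  image <- as_image_array(image)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(image)[1:2])) {
    stop("mask shape does not match image spatial shape")
  }
  if (!is_binary(mask)) stop("mask must be binary (0/1)")
  out <- image
  for (c in seq_len(dim(image)[3])) out[, , c] <- image[, , c] * mask
  out
}

#' Estimate the retinal field-of-view mask
#'
#' Thresholds the mean-channel intensity at 5% of its 99th percentile, keeps
#' the largest connected component, applies morphological closing (disc radius
#' 3 px) and fills holes. Intended for raw (unnormalized, non-negative)
#' images; ground-truth masks should be preferred when available.
#'
#' @param raw_image `[H, W, 3]` array with intensities in \[0, 1\].
#' @return Binary `[H, W]` integer matrix.
#' @export
estimate_fov_mask <- function(raw_image) {
  raw_image <- as_image_array(raw_image)
  stopifnot(length(dim(raw_image)) == 3)
  a <- (raw_image[, , 1] + raw_image[, , 2] + raw_image[, , 3]) / 3
  thr <- 0.05 * stats::quantile(a, 0.99, names = FALSE)
  bw <- a > thr
  if (!any(bw)) stop("FOV estimation failed: threshold removed every pixel")
  lab <- EBImage::bwlabel(bw)
  tab <- tabulate(lab[lab > 0])
  keep <- lab == which.max(tab)
  closed <- EBImage::closing(keep, EBImage::makeBrush(7, shape = "disc"))
  filled <- EBImage::fillHull(closed)
  matrix(as.integer(filled > 0), nrow(a), ncol(a))
}

#' Bilinear image resizing
#'
#' @param image `[H, W, C]` array or `[H, W]` matrix.
#' @param target_size Output side length in pixels.
#' @param binary If `TRUE`, re-binarize the result at 0.5 (for masks).
#' @return Resized array/matrix.
#' @export
resize_image <- function(image, target_size, binary = FALSE) {
  if (all(dim(image)[1:2] == target_size) && !binary) return(image)
  if (all(dim(image)[1:2] == target_size) && binary) {
    return(matrix(as.integer(image > 0.5), target_size, target_size))
  }
  out <- EBImage::resize(image, w = target_size, h = target_size)
  out <- as.array(out)
  if (binary) out <- matrix(as.integer(out > 0.5), target_size, target_size)
  out
}

#' Extract flattened patch tokens
#'
#' Cuts the image into the grid's non-overlapping squares and flattens each to
#' a vector of length `patch_dim`, in row-major patch order (top-left patch
#' first, rows before columns). Exactly inverted by [reassemble_patches()].
#'
#' @param image `[H, W, C]` array with `H = W = grid$target_size`.
#' @param grid A [patch_grid()].
#' @return `n_patches x patch_dim` matrix; row `i` is patch token `z_i`.
#' @export
extract_patches <- function(image, grid) {
  image <- as_image_array(image)
  d <- dim(image)
  if (d[1] != grid$target_size || d[2] != grid$target_size) {
    stop("image is not at the grid's target size; resize first")
  }
  P <- grid$patch_size
  out <- matrix(0, grid$n_patches, grid$patch_dim)
  for (gr in seq_len(grid$grid_rows)) {
    rows <- ((gr - 1) * P + 1):(gr * P)
    for (gc in seq_len(grid$grid_cols)) {
      cols <- ((gc - 1) * P + 1):(gc * P)
      i <- (gr - 1) * grid$grid_cols + gc
      out[i, ] <- as.vector(image[rows, cols, , drop = FALSE])
    }
  }
  out
}

#' @rdname extract_patches
#' @param patches `n_patches x patch_dim` matrix as returned by
#'   [extract_patches()].
#' @export
reassemble_patches <- function(patches, grid) {
  P <- grid$patch_size
  img <- array(0, dim = c(grid$target_size, grid$target_size, grid$n_channels))
  for (gr in seq_len(grid$grid_rows)) {
    rows <- ((gr - 1) * P + 1):(gr * P)
    for (gc in seq_len(grid$grid_cols)) {
      cols <- ((gc - 1) * P + 1):(gc * P)
      i <- (gr - 1) * grid$grid_cols + gc
      img[rows, cols, ] <- array(patches[i, ], dim = c(P, P, grid$n_channels))
    }
  }
  img
}

#' Full preprocessing pipeline for one image
#'
#' Normalize (training-set channel stats), mask to the FOV, resize to the
#' grid's target resolution (mask re-binarized at 0.5), and extract patch
#' tokens — in that order.
#'
#' @param image `[H, W, C]` array or `fundus_sample`.
#' @param stats A [fit_channel_stats()] result.
#' @param grid A [patch_grid()].
#' @param fov_mask Optional binary mask; if `NULL` and `image` is a
#'   `fundus_sample` its ground-truth mask is used, otherwise the mask is
#'   estimated from the raw image.
#' @return List with `patches` (`n_patches x patch_dim`), `mask` (resized
#'   binary matrix), and `image` (the resized masked image).
#' @export
preprocess_image <- function(image, stats, grid, fov_mask = NULL) {
  raw <- as_image_array(image)
  if (is.null(fov_mask)) {
    fov_mask <- if (inherits(image, "fundus_sample")) image$fov_mask else
      estimate_fov_mask(raw)
  }
  norm <- normalize_channels(raw, stats)
  masked <- apply_fov_mask(norm, fov_mask)
  resized <- resize_image(masked, grid$target_size)
  mask_r <- resize_image(fov_mask, grid$target_size, binary = TRUE)
  list(patches = extract_patches(resized, grid),
       mask = mask_r, image = resized)
}

#' Serialize / restore channel statistics
#'
#' @param stats A `channel_stats` object.
#' @param path JSON file path.
#' @return `write_channel_stats` returns `path` invisibly;
#'   `read_channel_stats` returns a `channel_stats` object.
#' @export
write_channel_stats <- function(stats, path) {
  jsonlite::write_json(list(means = stats$means, sds = stats$sds,
                            n_images = stats$n_images),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channel_stats
#' @export
read_channel_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(means = x$means, sds = x$sds, n_images = x$n_images),
            class = "channel_stats")
}
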