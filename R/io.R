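#' Write a synthetic dataset to disk
#'
#' Images are written as 8-bit PNG (or float32 TIFF), FOV and lesion masks as
#' single-channel PNG, labels and group ids as one CSV (`file`, `split`,
#' `group_id`, `severity`, one 0/1 column per class), and the generator
#' config plus seed as a JSON manifest.
#'
#' @param dataset A `fundus_dataset`.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @return `dir`, invisibly.
#' @export
write_fundus_dataset <- function(dataset, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "fundus_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  config <- attr(dataset, "config")
  rows <- list()
  idx <- 0L
  for (split in c("train", "validation", "test")) {
    for (s in dataset[[split]]) {
      idx <- idx + 1L
      fn <- sprintf("sample%04d.%s", idx, ifelse(format == "png", "png", "tif"))
      if (format == "png") {
        png::writePNG(s$image, file.path(dir, "images", fn))
      } else {
        tiff::writeTIFF(s$image, file.path(dir, "images", fn),
                        bits.per.sample = 32L)
      }
      png::writePNG(s$fov_mask + 0, file.path(dir, "masks",
                                              sub("\\.\\w+$", "_fov.png", fn)))
      png::writePNG(s$lesion_mask + 0,
                    file.path(dir, "masks",
                              sub("\\.\\w+$", "_lesion.png", fn)))
      rows[[idx]] <- cbind(
        data.frame(file = fn, split = split, group_id = s$group_id,
                   severity = s$severity),
        as.data.frame(as.list(s$labels)))
    }
  }
  labels_df <- do.call(rbind, rows)
  write.csv(labels_df, file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- list(
    config = unclass(config),
    seed = attr(dataset, "seed"),
    format = format,
    n_samples = idx,
    counts = list(train = length(dataset$train),
                  validation = length(dataset$validation),
                  test = length(dataset$test)),
    class_names = dataset_label_names(dataset))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

dataset_label_names <- function(dataset) {
  all <- c(dataset$train, dataset$validation, dataset$test)
  names(all[[1]]$labels)
}

#' Read a dataset written by [write_fundus_dataset()]
#'
#' @param dir Dataset directory containing `images/`, `masks/`, `labels.csv`
#'   and `manifest.json`.
#' @return A `fundus_dataset`.
#' @export
read_fundus_dataset <- function(dir) {
  if (!file.exists(file.path(dir, "manifest.json"))) {
    stop("no dataset manifest under '", dir,
         "'; run the simulate command first")
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  labels_df <- read.csv(file.path(dir, "labels.csv"))
  class_names <- manifest$class_names
  parts <- list(train = list(), validation = list(), test = list())
  for (i in seq_len(nrow(labels_df))) {
    fn <- labels_df$file[i]
    img <- if (manifest$format == "png") {
      png::readPNG(file.path(dir, "images", fn))
    } else {
      arr <- tiff::readTIFF(file.path(dir, "images", fn))
      arr
    }
    fov <- round(png::readPNG(file.path(dir, "masks",
                                        sub("\\.\\w+$", "_fov.png", fn))))
    les <- round(png::readPNG(file.path(dir, "masks",
                                        sub("\\.\\w+$", "_lesion.png", fn))))
    labels <- as.integer(labels_df[i, class_names])
    names(labels) <- class_names
    s <- structure(list(
      image = img, fov_mask = matrix(as.integer(fov), nrow(fov), ncol(fov)),
      lesion_mask = matrix(as.integer(les), nrow(les), ncol(les)),
      labels = labels, severity = labels_df$severity[i],
      group_id = labels_df$group_id[i],
      lesion_log = NULL), class = "fundus_sample")
    parts[[labels_df$split[i]]][[length(parts[[labels_df$split[i]]]) + 1]] <- s
  }
  cfg <- manifest$config
  config <- synthetic_config(
    image_size = cfg$image_size, fov_radius_frac = cfg$fov_radius_frac,
    lesion_classes = lapply(cfg$lesion_classes, function(x) {
      list(name = x$name, kind = x$kind, prevalence = x$prevalence,
           count_range = unlist(x$count_range),
           radius_range_px = unlist(x$radius_range_px))
    }),
    vessel_count = cfg$vessel_count,
    illumination_gradient_strength = cfg$illumination_gradient_strength,
    noise_sd = cfg$noise_sd, severity_step = cfg$severity_step,
    cooccurrence_boost = cfg$cooccurrence_boost, seed = cfg$seed)
  structure(parts, class = "fundus_dataset", config = config,
            seed = manifest$seed)
}

#' Write an attention-saliency heatmap overlay
#'
#' Upsamples the patch-level saliency to image resolution and overlays it on
#' the image's red channel.
#'
#' @param image `[H, W, C]` array in \[0, 1\].
#' @param saliency Length-`n_patches` saliency vector.
#' @param grid A [patch_grid()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_saliency_overlay <- function(image, saliency, grid, path) {
  sal_m <- matrix(saliency, grid$grid_rows, grid$grid_cols, byrow = TRUE)
  sal_m <- sal_m / max(sal_m)
  heat <- resize_image(sal_m, grid$target_size)
  heat <- pmin(pmax(heat, 0), 1)
  img <- resize_image(as_image_array(image), grid$target_size)
  out <- img
  out[, , 1] <- pmin(1, img[, , 1] * 0.5 + heat * 0.5)
  out[, , 2] <- img[, , 2] * 0.5
  out[, , 3] <- img[, , 3] * 0.5
  png::writePNG(out, path)
  invisible(path)
}

# Append one machine-readable event to a run's JSONL log, and mirror a short
# line into the plain-text log.
log_event <- function(dir, type, data = list()) {
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                type = type), data)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = file.path(dir, "events.jsonl"), append = TRUE)
  cat(rec$time, " [", type, "]\n", sep = "",
      file = file.path(dir, "run.log"), append = TRUE)
  invisible(NULL)
}
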