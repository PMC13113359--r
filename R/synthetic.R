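#' Configuration for the synthetic fundus generator
#'
#' Describes the fundus-like images the generator emulates: a circular retinal
#' field of view (FOV) on a dark background, a smooth illumination gradient,
#' an optic-disc blob, vessel-like curvilinear structures, and planted lesions
#' with known ground truth. Lesions come in two stylized morphologies:
#' `bright_spot` (a Gaussian-profile brightening of the red/green channels, an
#' exudate surrogate) and `dark_blob` (an intensity depression, a hemorrhage
#' surrogate). Lesion presence drives both the per-class binary label vector
#' and an ordinal severity grade.
#'
#' @param image_size Pixels per side of the (square) image.
#' @param n_channels Number of color channels; fixed at 3.
#' @param fov_radius_frac FOV radius as a fraction of half the image size,
#'   in (0, 1].
#' @param lesion_classes List of lesion class descriptors, each a list with
#'   `name`, `kind` (`"bright_spot"` or `"dark_blob"`), `prevalence` in
#'   \[0, 1\], `count_range` (length-2 integer), and `radius_range_px`
#'   (length-2 numeric, pixels).
#' @param vessel_count Number of vessel-like random-walk structures.
#' @param illumination_gradient_strength Dimensionless strength (>= 0) of a
#'   linear illumination ramp across the FOV.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param severity_step Lesion count per severity grade: the grade is
#'   `min(4, floor(total_lesions / severity_step))`, a 5-level staircase
#'   mirroring clinical severity grading.
#' @param cooccurrence_boost Added to a class's prevalence when an earlier
#'   class is already present, emulating co-occurring diseases; 0 disables.
#' @param seed Integer seed; the same (config, seed) pair yields bit-identical
#'   samples.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(image_size = 64L,
                             n_channels = 3L,
                             fov_radius_frac = 0.9,
                             lesion_classes = default_lesion_classes(),
                             vessel_count = 6L,
                             illumination_gradient_strength = 0.3,
                             noise_sd = 0.02,
                             severity_step = 2L,
                             cooccurrence_boost = 0,
                             seed = 1L) {
  stopifnot(image_size >= 8, n_channels == 3L,
            fov_radius_frac > 0, fov_radius_frac <= 1,
            vessel_count >= 0, illumination_gradient_strength >= 0,
            noise_sd >= 0, severity_step >= 1)
  for (cls in lesion_classes) {
    stopifnot(is.character(cls$name),
              cls$kind %in% c("bright_spot", "dark_blob"),
              cls$prevalence >= 0, cls$prevalence <= 1,
              length(cls$count_range) == 2, cls$count_range[1] >= 1,
              length(cls$radius_range_px) == 2, cls$radius_range_px[1] > 0)
    if (max(cls$radius_range_px) >= fov_radius_frac * image_size / 2) {
      stop("lesion radius range for class '", cls$name,
           "' exceeds the FOV radius")
    }
  }
  structure(list(
    image_size = as.integer(image_size),
    n_channels = 3L,
    fov_radius_frac = fov_radius_frac,
    lesion_classes = lesion_classes,
    vessel_count = as.integer(vessel_count),
    illumination_gradient_strength = illumination_gradient_strength,
    noise_sd = noise_sd,
    severity_step = as.integer(severity_step),
    cooccurrence_boost = cooccurrence_boost,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default lesion class set
#'
#' Two co-occurring lesion classes: a bright exudate-like class and a dark
#' hemorrhage-like class, with prevalences reflecting the imbalanced screening
#' setting (diseased cases are the minority).
#'
#' @param image_size Image size the radius defaults are scaled for.
#' @return List of lesion class descriptors.
#' @export
default_lesion_classes <- function(image_size = 64L) {
  r <- image_size / 64
  list(
    list(name = "exudate_like", kind = "bright_spot", prevalence = 0.40,
         count_range = c(1L, 4L), radius_range_px = c(2, 4.5) * r),
    list(name = "hemorrhage_like", kind = "dark_blob", prevalence = 0.30,
         count_range = c(1L, 4L), radius_range_px = c(2, 4.5) * r)
  )
}

# Squared-distance field from a center, on the pixel grid (row = y, col = x).
dist2_field <- function(s, cy, cx) {
  yy <- matrix(seq_len(s), s, s)
  xx <- matrix(seq_len(s), s, s, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2
}

#' Generate one labeled synthetic fundus sample
#'
#' Renders a 3-channel fundus-like image in \[0, 1\] together with its binary
#' FOV mask, the union mask of all planted lesions, a per-lesion log, a binary
#' label vector (class present iff at least one lesion of that class was
#' planted), and an ordinal severity grade. Lesion centers are
#' rejection-sampled so every lesion disc lies fully inside the FOV and does
#' not overlap previously planted lesions, which keeps the per-lesion pixel
#' areas additive.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param group_id Integer patient surrogate carried on the sample.
#' @return An object of class `fundus_sample` with fields `image`, `fov_mask`,
#'   `lesion_mask`, `labels`, `severity`, `group_id`, `lesion_log`.
#' @export
generate_sample <- function(config, seed = config$seed, group_id = 0L) {
  stopifnot(inherits(config, "synthetic_config"))
  s <- config$image_size
  with_seed(seed, {
    ctr <- (s + 1) / 2
    fov_r <- config$fov_radius_frac * s / 2
    d2 <- dist2_field(s, ctr, ctr)
    fov <- (d2 <= fov_r^2) * 1L
    dist_frac <- sqrt(d2) / fov_r

    # Base retinal coloring with mild radial vignetting.
    base_col <- c(0.62, 0.40, 0.18)
    vignette <- 1 - 0.25 * pmin(dist_frac, 1)^2
    img <- array(0.01, dim = c(s, s, 3L))
    for (c in 1:3) img[, , c] <- img[, , c] + fov * base_col[c] * vignette

    # Linear illumination ramp in a random direction across the FOV.
    if (config$illumination_gradient_strength > 0) {
      ang <- runif(1, 0, 2 * pi)
      yy <- matrix(seq_len(s), s, s); xx <- matrix(seq_len(s), s, s, byrow = TRUE)
      proj <- ((yy - ctr) * sin(ang) + (xx - ctr) * cos(ang)) / fov_r
      ramp <- 1 + config$illumination_gradient_strength * 0.5 * proj
      for (c in 1:3) img[, , c] <- img[, , c] * ifelse(fov == 1, ramp, 1)
    }

    # Optic disc: bright blob offset from center.
    od_ang <- runif(1, 0, 2 * pi)
    od_r <- 0.55 * fov_r
    od_cy <- ctr + od_r * sin(od_ang); od_cx <- ctr + od_r * cos(od_ang)
    od_sigma <- s / 14
    od_prof <- exp(-dist2_field(s, od_cy, od_cx) / (2 * od_sigma^2))
    od_amp <- c(0.25, 0.24, 0.12)
    for (c in 1:3) img[, , c] <- img[, , c] + fov * od_amp[c] * od_prof

    # Vessel-like curvilinear structures: correlated random walks radiating
    # from the optic disc, drawn as intensity depressions (mainly green).
    if (config$vessel_count > 0) {
      n_steps <- ceiling(1.6 * fov_r)
      for (v in seq_len(config$vessel_count)) {
        heading <- runif(1, 0, 2 * pi)
        turns <- cumsum(rnorm(n_steps, 0, 0.15))
        ys <- od_cy + cumsum(sin(heading + turns))
        xs <- od_cx + cumsum(cos(heading + turns))
        iy <- round(ys); ix <- round(xs)
        keep <- iy >= 1 & iy <= s & ix >= 1 & ix <= s
        iy <- iy[keep]; ix <- ix[keep]
        if (length(iy) == 0) next
        pix <- unique(cbind(iy, ix))
        for (c in 1:3) {
          ch <- img[, , c]
          ch[pix] <- ch[pix] - c(0.10, 0.22, 0.06)[c] * fov[pix]
          img[, , c] <- ch
        }
      }
    }

    # Plant lesions class by class, rejection-sampling non-overlapping
    # centers strictly inside the FOV.
    lesion_mask <- matrix(0L, s, s)
    labels <- integer(length(config$lesion_classes))
    names(labels) <- vapply(config$lesion_classes, `[[`, "", "name")
    log_rows <- list()
    planted <- matrix(numeric(0), ncol = 3)  # cy, cx, r
    any_present <- FALSE
    for (ci in seq_along(config$lesion_classes)) {
      cls <- config$lesion_classes[[ci]]
      prev <- cls$prevalence +
        if (any_present) config$cooccurrence_boost else 0
      present <- runif(1) < min(prev, 1)
      if (!present) next
      n_les <- sample(seq(cls$count_range[1], cls$count_range[2]), 1L)
      for (k in seq_len(n_les)) {
        r <- runif(1, cls$radius_range_px[1], cls$radius_range_px[2])
        placed <- FALSE
        for (try in 1:100) {
          u_ang <- runif(1, 0, 2 * pi)
          u_rad <- sqrt(runif(1)) * (fov_r - r - 1)
          cy <- ctr + u_rad * sin(u_ang); cx <- ctr + u_rad * cos(u_ang)
          if (nrow(planted) > 0 &&
              any(sqrt((planted[, 1] - cy)^2 + (planted[, 2] - cx)^2) <=
                  planted[, 3] + r + 1)) next
          placed <- TRUE
          break
        }
        if (!placed) next
        planted <- rbind(planted, c(cy, cx, r))
        d2l <- dist2_field(s, cy, cx)
        disc <- d2l <= r^2
        lesion_mask[disc] <- 1L
        prof <- exp(-d2l / (2 * (r / 1.8)^2))
        amp <- runif(1, 0.30, 0.50)
        if (cls$kind == "bright_spot") {
          img[, , 1] <- img[, , 1] + fov * 0.8 * amp * prof
          img[, , 2] <- img[, , 2] + fov * amp * prof
        } else {
          for (c in 1:3) {
            img[, , c] <- img[, , c] - fov * c(0.9, 1, 0.5)[c] * amp * prof
          }
        }
        labels[ci] <- 1L
        log_rows[[length(log_rows) + 1]] <- data.frame(
          class = cls$name, cy = cy, cx = cx, radius = r, area = sum(disc))
      }
      any_present <- any_present || labels[ci] == 1L
    }

    if (config$noise_sd > 0) {
      img <- img + array(rnorm(s * s * 3, 0, config$noise_sd), dim = dim(img))
    }
    img[img < 0] <- 0; img[img > 1] <- 1

    lesion_log <- if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(class = character(), cy = numeric(), cx = numeric(),
                 radius = numeric(), area = integer())
    severity <- min(4L, nrow(lesion_log) %/% config$severity_step)

    structure(list(
      image = img,
      fov_mask = fov,
      lesion_mask = lesion_mask,
      labels = labels,
      severity = severity,
      group_id = as.integer(group_id),
      lesion_log = lesion_log
    ), class = "fundus_sample")
  })
}

#' Generate a patient-level partitioned synthetic dataset
#'
#' Samples are organized into groups (patient surrogates, `samples_per_group`
#' images each, e.g. two eyes) and groups — never individual samples — are
#' allocated to the training/validation/test partitions, so no group spans two
#' partitions. Partition sizes in groups follow the requested fractions by
#' largest-remainder rounding (within one group of exact).
#'
#' @param config A [synthetic_config()].
#' @param n Number of samples (>= 10).
#' @param split_fracs Length-3 non-negative vector summing to 1:
#'   train/validation/test fractions.
#' @param seed Integer seed controlling both sample content and partitioning.
#' @param samples_per_group Images per patient surrogate.
#' @return Object of class `fundus_dataset`: a list with elements `train`,
#'   `validation`, `test` (lists of `fundus_sample`), plus the config and seed
#'   as attributes.
#' @export
generate_dataset <- function(config, n, split_fracs = c(0.7, 0.1, 0.2),
                             seed = config$seed, samples_per_group = 2L) {
  stopifnot(inherits(config, "synthetic_config"), n >= 10,
            length(split_fracs) == 3, all(split_fracs >= 0),
            abs(sum(split_fracs) - 1) < 1e-8, samples_per_group >= 1)
  group_of <- rep(seq_len(ceiling(n / samples_per_group)),
                  each = samples_per_group)[seq_len(n)]
  n_groups <- max(group_of)
  n_parts <- sum(split_fracs > 0)
  if (n_groups < n_parts) {
    stop("fewer distinct groups (", n_groups, ") than partitions (", n_parts, ")")
  }

  # Largest-remainder allocation of groups to partitions.
  exact <- split_fracs * n_groups
  counts <- floor(exact)
  rem <- n_groups - sum(counts)
  if (rem > 0) {
    order_rem <- order(exact - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  # Guarantee every non-empty partition gets at least one group.
  for (p in which(split_fracs > 0 & counts == 0)) {
    donor <- which.max(counts)
    counts[donor] <- counts[donor] - 1
    counts[p] <- counts[p] + 1
  }

  part_of_group <- with_seed(derive_seed(seed, 0L), {
    shuffled <- sample(n_groups)
    assign_vec <- integer(n_groups)
    idx <- 1
    for (p in 1:3) {
      if (counts[p] > 0) {
        assign_vec[shuffled[idx:(idx + counts[p] - 1)]] <- p
        idx <- idx + counts[p]
      }
    }
    assign_vec
  })

  samples <- lapply(seq_len(n), function(i) {
    generate_sample(config, seed = derive_seed(seed, i), group_id = group_of[i])
  })
  parts <- lapply(1:3, function(p) {
    samples[part_of_group[group_of] == p]
  })
  structure(list(train = parts[[1]], validation = parts[[2]], test = parts[[3]]),
            class = "fundus_dataset", config = config, seed = as.integer(seed))
}

#' @export
print.fundus_dataset <- function(x, ...) {
  cat("fundus_dataset:",
      length(x$train), "train /", length(x$validation), "validation /",
      length(x$test), "test samples\n")
  invisible(x)
}

dataset_labels <- function(samples) {
  C <- length(samples[[1]]$labels)
  m <- matrix(0, length(samples), C)
  for (i in seq_along(samples)) m[i, ] <- samples[[i]]$labels
  colnames(m) <- names(samples[[1]]$labels)
  m
}
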