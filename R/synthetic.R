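# Synthetic histology-like fixtures with known ground truth. The generator
# emulates the visual structure the segmentation pipeline cares about --
# textured eosin-pink stroma, denser purple tumor regions with scattered
# dark nuclei, smooth irregular tumor boundaries -- without claiming
# histological realism. Every other module is testable against it offline.

#' Configuration of the synthetic fixture generator
#'
#' Defaults mirror the study conditions the pipeline targets: 1024 x 1024
#' regions of interest mined into 256 x 256 patches with half overlap, 31
#' pseudo-slide sources. The `difficulty` knob moves the tumor color
#' distribution toward the background and raises texture noise: at 0 the
#' classes are separable by color alone, at 1 they overlap heavily.
#'
#' @param n_sources number of pseudo-slides (sources) in a corpus.
#' @param roi_size ROI side length in pixels.
#' @param tile patch side length used when mining the corpus.
#' @param n_blobs tumor regions per ROI.
#' @param blob_scale typical tumor region radius in pixels (default
#'   `roi_size / 6`).
#' @param difficulty class-contrast difficulty in \[0, 1\].
#' @param bg_color,fg_color mean RGB of background stroma and tumor tissue
#'   at difficulty 0, in \[0, 1\].
#' @param noise_sd base standard deviation of the smooth texture fields.
#' @param nuclei_density nuclei per pixel in background tissue (tumor tissue
#'   gets 4 times this).
#' @param contour_vertices vertices per polygon annotation approximating a
#'   tumor boundary.
#' @param seed integer seed; identical configuration and seed reproduce the
#'   corpus exactly.
#' @return object of class `fixture_config`.
#' @export
fixture_config <- function(n_sources = 31L, roi_size = 1024L, tile = 256L,
                           n_blobs = 3L, blob_scale = roi_size / 6,
                           difficulty = 0, bg_color = c(0.91, 0.75, 0.82),
                           fg_color = c(0.55, 0.40, 0.62), noise_sd = 0.035,
                           nuclei_density = 2e-4, contour_vertices = 72L,
                           seed = 1L) {
  stopifnot(difficulty >= 0, difficulty <= 1, n_blobs >= 0)
  structure(
    list(n_sources = as.integer(n_sources), roi_size = as.integer(roi_size),
         tile = as.integer(tile), n_blobs = as.integer(n_blobs),
         blob_scale = blob_scale, difficulty = difficulty,
         bg_color = bg_color, fg_color = fg_color, noise_sd = noise_sd,
         nuclei_density = nuclei_density,
         contour_vertices = as.integer(contour_vertices),
         seed = as.integer(seed)),
    class = "fixture_config"
  )
}

# smooth unit-sd noise field: white noise blurred with a Gaussian kernel
smooth_field <- function(h, w, sigma = 8) {
  f <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma = sigma)
  f / stats::sd(f)
}

# radial boundary of one tumor blob: ellipse-like base radius with
# low-frequency perturbation so the contour is a simple polygon
blob_boundary <- function(radius) {
  harmonics <- 2:4
  amp <- stats::runif(length(harmonics), 0, 0.45) / harmonics
  phase <- stats::runif(length(harmonics), 0, 2 * pi)
  ecc <- stats::runif(1, 0, 0.25)
  ecc_phase <- stats::runif(1, 0, pi)
  function(theta) {
    r <- radius * (1 + ecc * cos(2 * (theta - ecc_phase)))
    for (k in seq_along(harmonics))
      r <- r + radius * amp[k] * sin(harmonics[k] * theta + phase[k])
    r
  }
}

#' Generate one synthetic ROI with exact ground truth
#'
#' Draws `n_blobs` smoothly deformed elliptical tumor regions as darker,
#' purple-ish, nuclei-dense texture on a pink stroma background. Returns the
#' exact per-pixel mask (evaluated from the blob boundary functions) plus a
#' polygonal contour annotation per blob, suitable for
#' [rasterize_mask()].
#'
#' @param cfg a [fixture_config()].
#' @param source_id identifier recorded on the ROI.
#' @param seed optional seed; identical `cfg` and `seed` reproduce the ROI
#'   bit for bit. `NULL` draws from the current RNG stream (as inside
#'   [build_corpus()], which seeds once for the whole corpus).
#' @return list with `image` (H x W x 3, \[0, 1\]), `mask` (H x W binary),
#'   `bbox`, `source_id` and `annotations` (list of `polygon`/`label`).
#' @export
generate_roi <- function(cfg, source_id = "roi", seed = NULL) {
  stopifnot(inherits(cfg, "fixture_config"))
  if (!is.null(seed)) set.seed(seed)
  s <- cfg$roi_size
  if (cfg$n_blobs > 0 && cfg$n_blobs * pi * (1.6 * cfg$blob_scale)^2 > 4 * s^2)
    stop("requested tumor blobs exceed the ROI area budget; reduce n_blobs ",
         "or blob_scale")
  d <- cfg$difficulty
  fg_col <- cfg$bg_color + (cfg$fg_color - cfg$bg_color) * (1 - 0.85 * d)
  sdv <- cfg$noise_sd * (1 + 3 * d)

  mask <- matrix(0L, s, s)
  annotations <- list()
  xg <- matrix(rep(seq_len(s) - 0.5, each = s), s, s)   # x per column
  yg <- matrix(rep(seq_len(s) - 0.5, s), s, s)          # y per row
  for (b in seq_len(cfg$n_blobs)) {
    radius <- cfg$blob_scale * stats::runif(1, 0.7, 1.3)
    margin <- min(1.6 * radius, s / 2 - 1)
    cx <- stats::runif(1, margin, s - margin)
    cy <- stats::runif(1, margin, s - margin)
    boundary <- blob_boundary(radius)
    theta <- atan2(yg - cy, xg - cx)
    rr <- sqrt((xg - cx)^2 + (yg - cy)^2)
    mask[rr <= boundary(theta)] <- 1L
    tv <- seq(0, 2 * pi, length.out = cfg$contour_vertices + 1L)[-1L]
    annotations[[b]] <- list(
      label = "positive",
      polygon = cbind(x = cx + boundary(tv) * cos(tv),
                      y = cy + boundary(tv) * sin(tv))
    )
  }

  img <- array(0, c(s, s, 3L))
  for (ch in 1:3) {
    base <- cfg$bg_color[ch] + (fg_col[ch] - cfg$bg_color[ch]) * mask
    img[, , ch] <- base + sdv * smooth_field(s, s) + (cfg$noise_sd / 2) *
      stats::rnorm(s * s)
  }

  # scattered dark "nuclei": denser inside tumor tissue
  n_bg <- stats::rpois(1, cfg$nuclei_density * s * s)
  n_fg <- stats::rpois(1, 4 * cfg$nuclei_density * sum(mask))
  nx <- c(stats::runif(n_bg, 1, s), numeric(0))
  ny <- c(stats::runif(n_bg, 1, s), numeric(0))
  if (n_fg > 0 && sum(mask) > 0) {
    inside <- which(mask == 1L)
    pick <- sample(inside, n_fg, replace = TRUE)
    ny <- c(ny, ((pick - 1L) %% s) + stats::runif(n_fg, 0, 1))
    nx <- c(nx, ((pick - 1L) %/% s) + stats::runif(n_fg, 0, 1))
  }
  nucleus_col <- c(0.30, 0.15, 0.45)
  for (i in seq_along(nx)) {
    r <- stats::runif(1, 1.5, 3)
    rows <- max(1, floor(ny[i] - r)):min(s, ceiling(ny[i] + r))
    colsx <- max(1, floor(nx[i] - r)):min(s, ceiling(nx[i] + r))
    for (ch in 1:3) {
      sub <- img[rows, colsx, ch]
      dd <- outer(rows - ny[i], colsx - nx[i], function(a, b) a^2 + b^2)
      w <- pmax(0, 1 - dd / r^2) * 0.8
      img[rows, colsx, ch] <- sub * (1 - w) + nucleus_col[ch] * w
    }
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, mask = mask, bbox = c(0L, 0L, s, s),
       source_id = source_id, annotations = annotations)
}

#' Build a split corpus of mined patches
#'
#' Generates `cfg$n_sources` ROIs, mines half-overlap training patches from
#' each ([mine_training_patches()]), and assigns whole sources to
#' train/validation/test so the splits are source-disjoint (patches from one
#' pseudo-slide never span splits). Default allocation scales the 26/5
#' train+validation/test source split of a 31-slide corpus.
#'
#' @param cfg a [fixture_config()].
#' @param dir optional directory; when given, patches and masks are written
#'   as PNG files and the manifest paths point at them, otherwise patch
#'   arrays are kept in memory on the manifest rows.
#' @param n_test,n_val number of sources held out for testing/validation;
#'   defaults scale the 26/5 allocation (test) and a fifth of the remainder
#'   (validation).
#' @param min_positive keep rule passed to [mine_training_patches()]:
#'   minimum positive pixels for a patch to enter the corpus. The default 1
#'   keeps every patch with any tumor surface; desk-scale learnability
#'   corpora use a fraction of the tile area so kept patches carry a
#'   resolvable tumor region rather than a boundary sliver.
#' @return object of class `split_manifest`: a list with `patches` (named
#'   by split), `sources` (split -> source ids), `counts`, `seed`.
#' @export
build_corpus <- function(cfg, dir = NULL, n_test = NULL, n_val = NULL,
                         min_positive = 1L) {
  stopifnot(inherits(cfg, "fixture_config"))
  if (cfg$n_sources < 3L) stop("need at least 3 sources (one per split)")
  set.seed(cfg$seed)
  if (is.null(n_test)) n_test <- max(1L, round(cfg$n_sources * 5L / 31L))
  if (is.null(n_val)) n_val <- max(1L, round((cfg$n_sources - n_test) / 5.2))
  n_train <- cfg$n_sources - n_test - n_val
  if (n_train < 1L) stop("split allocation leaves no training sources")
  src_ids <- sprintf("source%02d", seq_len(cfg$n_sources))
  split_of <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))

  patches <- list(train = list(), val = list(), test = list())
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(cfg$n_sources)) {
    roi <- generate_roi(cfg, source_id = src_ids[i])
    mined <- mine_training_patches(roi, tile = cfg$tile,
                                   stride = cfg$tile %/% 2L,
                                   min_positive = min_positive)
    sp <- split_of[i]
    for (k in seq_along(mined)) {
      p <- mined[[k]]
      p$source_id <- src_ids[i]
      p$patch_id <- sprintf("%s_p%03d", src_ids[i], k)
      if (!is.null(dir)) {
        p$image_path <- file.path(dir, paste0(p$patch_id, ".png"))
        p$mask_path <- file.path(dir, paste0(p$patch_id, "_mask.png"))
        write_image(p$image, p$image_path)
        write_mask(p$mask, p$mask_path)
        p$image <- NULL
        p$mask <- NULL
      }
      patches[[sp]][[length(patches[[sp]]) + 1L]] <- p
    }
  }
  man <- structure(
    list(patches = patches,
         sources = split(src_ids, factor(split_of, c("train", "val", "test"))),
         counts = vapply(patches, length, 1L),
         tile = cfg$tile, seed = cfg$seed, dir = dir),
    class = "split_manifest"
  )
  if (!is.null(dir)) write_manifest_csv(man, file.path(dir, "manifest.csv"))
  man
}

#' @export
print.split_manifest <- function(x, ...) {
  cat("split manifest (seed ", x$seed, "):\n", sep = "")
  for (sp in names(x$patches))
    cat(sprintf("  %-5s %3d sources, %4d patches\n", sp,
                length(x$sources[[sp]]), x$counts[[sp]]))
  invisible(x)
}

write_manifest_csv <- function(manifest, path) {
  rows <- do.call(rbind, lapply(names(manifest$patches), function(sp) {
    ps <- manifest$patches[[sp]]
    if (length(ps) == 0L) return(NULL)
    data.frame(
      split = sp,
      source_id = vapply(ps, `[[`, "", "source_id"),
      patch_id = vapply(ps, `[[`, "", "patch_id"),
      origin_y = vapply(ps, function(p) p$origin[1L], 0),
      origin_x = vapply(ps, function(p) p$origin[2L], 0),
      image_path = vapply(ps, function(p) p$image_path %||% "", ""),
      mask_path = vapply(ps, function(p) p$mask_path %||% "", "")
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Materialize the patches of one corpus split
#'
#' Returns the (image, mask) patch list of a split, reading the PNG files
#' back in when the corpus was written to disk.
#'
#' @param manifest a [build_corpus()] manifest.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return list of patches with `image`, `mask`, `origin`, `source_id`.
#' @export
split_patches <- function(manifest, split) {
  lapply(manifest$patches[[split]], function(p) {
    if (is.null(p[["image"]])) {   # [[ avoids partial matching image_path
      p$image <- read_image(p[["image_path"]])
      p$mask <- read_mask(p[["mask_path"]])
    }
    p
  })
}
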