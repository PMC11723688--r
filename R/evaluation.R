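# End-to-end benchmark harness: train a set of variants on one corpus,
# evaluate the best checkpoints on internal (and optionally external) test
# splits, emit the per-model report and the qualitative panel renderings.

#' Segment a large region with a trained network
#'
#' Patchifies the region into network-sized tiles (non-overlapping by
#' default), predicts each tile and recombines the tile masks into a
#' full-region prediction.
#'
#' @param net a [unet()] network or [unet_train()] fit.
#' @param image H x W x C region, at least one tile in each dimension.
#' @param stride tile stride; default non-overlapping. With overlap the
#'   tile foreground probabilities are averaged before thresholding.
#' @return binary mask of the region's size.
#' @export
segment_roi <- function(net, image, stride = NULL) {
  if (inherits(net, "unet_fit")) net <- best_network(net)
  tile <- net$config$input_size[1L]
  if (is.null(stride)) stride <- tile
  pieces <- patchify(image, tile = tile, stride = stride)
  probs <- predict_batch(net, pieces$tiles, type = "prob")
  fg <- lapply(probs, function(p) p[, , 2L])
  out <- unpatchify(pieces$grid, fg, binarize = FALSE)
  (out >= 0.5) * 1L
}

#' Benchmark a set of U-Net variants on a fixture corpus
#'
#' Trains each requested variant on the corpus' training split, selects the
#' best-validation-Dice checkpoint, and evaluates it on the internal test
#' split and, when given, an external corpus' test split (cross-corpus
#' testing). Emits one report row per variant with mean Dice accuracy,
#' mean IoU, parameter count and wall-clock timings (informational only --
#' they depend on the machine). A variant whose training fails is recorded
#' as a failed row and the run continues.
#'
#' @param variants character vector, subset of [unet_variants()].
#' @param corpus a [build_corpus()] manifest.
#' @param net_config a [unet_config()] matching the corpus patch size.
#' @param config a [train_config()].
#' @param external optional second corpus for external testing.
#' @param output_dir optional directory for CSV reports, run configuration
#'   (YAML) and difference-map panels of the first internal test patches.
#' @param n_panels number of test patches rendered as panels.
#' @return list with `internal` and (if requested) `external` report
#'   data.frames, plus `fits` (named list of `unet_fit`s).
#' @export
run_benchmark <- function(variants, corpus, net_config, config,
                          external = NULL, output_dir = NULL, n_panels = 0L) {
  stopifnot(all(variants %in% unet_variants()))
  train_set <- split_patches(corpus, "train")
  val_set <- split_patches(corpus, "val")
  test_set <- split_patches(corpus, "test")
  ext_set <- if (!is.null(external)) split_patches(external, "test")
  if (!is.null(output_dir))
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  empty_row <- function(v) data.frame(
    variant = v, accuracy = NA_real_, mean_iou = NA_real_,
    params_millions = NA_real_, epoch_train_time_s = NA_real_,
    eval_time_ms = NA_real_, status = "failed"
  )
  internal <- list()
  external_rows <- list()
  fits <- list()
  for (v in variants) {
    row <- tryCatch({
      net <- unet(v, net_config, seed = config$seed)
      t0 <- proc.time()[["elapsed"]]
      fit <- unet_train(net, train_set, val_set, config)
      train_time <- (proc.time()[["elapsed"]] - t0) / nrow(fit$log)
      fits[[v]] <- fit
      t1 <- proc.time()[["elapsed"]]
      ev <- evaluate_patches(fit, test_set)
      eval_ms <- 1000 * (proc.time()[["elapsed"]] - t1) / length(test_set)
      data.frame(
        variant = v, accuracy = ev$accuracy_percent, mean_iou = ev$mean_iou,
        params_millions = count_parameters(net) / 1e6,
        epoch_train_time_s = train_time, eval_time_ms = eval_ms,
        status = "ok"
      )
    }, error = function(e) {
      warning("variant ", v, " failed: ", conditionMessage(e))
      empty_row(v)
    })
    internal[[v]] <- row
    if (!is.null(ext_set)) {
      external_rows[[v]] <- if (identical(row$status, "ok")) {
        ee <- evaluate_patches(fits[[v]], ext_set)
        r <- row
        r$accuracy <- ee$accuracy_percent
        r$mean_iou <- ee$mean_iou
        r$eval_time_ms <- NA_real_
        r
      } else empty_row(v)
    }
  }
  internal <- do.call(rbind, internal)
  rownames(internal) <- NULL
  out <- list(internal = metrics_report(internal), fits = fits)
  if (!is.null(ext_set)) {
    ext <- do.call(rbind, external_rows)
    rownames(ext) <- NULL
    out$external <- metrics_report(ext)
  }
  if (!is.null(output_dir)) {
    metrics_report(out$internal, file.path(output_dir, "report_internal.csv"))
    if (!is.null(out$external))
      metrics_report(out$external, file.path(output_dir, "report_external.csv"))
    run_cfg <- list(variants = variants, seed = config$seed,
                    epochs = config$epochs, batch_size = config$batch_size,
                    lr = config$lr,
                    input_size = net_config$input_size,
                    depth = net_config$depth,
                    base_filters = net_config$base_filters)
    yaml::write_yaml(run_cfg, file.path(output_dir, "run_config.yaml"))
    if (n_panels > 0L && length(fits) > 0L) {
      fit1 <- fits[[1L]]
      for (i in seq_len(min(n_panels, length(test_set)))) {
        p <- test_set[[i]]
        pred <- predict_batch(fit1, p$image, type = "mask")
        render_panels(p$image, p$mask, pred,
                      out_dir = file.path(output_dir, "panels"),
                      prefix = sprintf("test%03d", i))
      }
    }
  }
  out
}

#' Render the six qualitative comparison panels for one region
#'
#' Writes the panel set used to inspect a prediction: (A) the original
#' image; (B) the image with the annotation contour drawn in blue; (C) the
#' ground-truth mask (deep blue on black); (D) the predicted mask; (E) the
#' prediction overlaid on the image; (F) the truth-vs-prediction difference
#' map (light blue intersection, deep blue false negatives, gray false
#' positives).
#'
#' @param image H x W x 3 region image.
#' @param truth,pred binary masks of matching size.
#' @param out_dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param annotations optional polygon annotations for panel B; when
#'   missing the contour is derived from the truth mask boundary.
#' @return named character vector of the six written PNG paths.
#' @export
render_panels <- function(image, truth, pred, out_dir, prefix = "roi",
                          annotations = NULL) {
  d <- dim(image)
  if (!identical(d[1:2], dim2(truth)[1:2]) ||
      !identical(dim2(truth), dim2(pred)))
    stop("image, truth and pred shapes do not match")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cols <- seg_colors()
  contoured <- image
  boundary <- mask_boundary(if (is.null(annotations)) truth else
    rasterize_mask(annotations, c(0, 0, d[2L], d[1L])))
  for (ch in 1:3) {
    plane <- contoured[, , ch]
    plane[boundary] <- cols$deep_blue[ch]
    contoured[, , ch] <- plane
  }
  files <- c(
    A = "original", B = "contoured", C = "truth_mask", D = "pred_mask",
    E = "overlay", F = "difference"
  )
  paths <- file.path(out_dir, sprintf("%s_%s_%s.png", prefix, names(files),
                                      files))
  names(paths) <- names(files)
  write_image(image, paths[["A"]])
  write_image(contoured, paths[["B"]])
  write_image(encode_mask_rgb(truth), paths[["C"]])
  write_image(encode_mask_rgb(pred), paths[["D"]])
  write_image(overlay(image, pred), paths[["E"]])
  write_image(difference_map(truth, pred), paths[["F"]])
  paths
}

# boundary pixels of a mask: positive pixels with at least one 4-neighbor
# background pixel
mask_boundary <- function(mask) {
  m <- as.matrix(mask) > 0
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  interior <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  m & !interior
}
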