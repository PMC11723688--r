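# Patch tiling: overlap mining for training corpora and the
# patchify/unpatchify inference path over large regions.

#' Tile grid over a source image
#'
#' Computes the row-major grid of `tile` x `tile` windows at the given
#' `stride` covering a source of size `source_size`, together with the
#' bottom/right reflect padding needed so the windows cover it exactly.
#' With `stride == tile` the windows partition the padded source.
#' Coordinates are 0-based (row, col), windows half-open.
#'
#' @param source_size integer (H, W) of the source in pixels.
#' @param tile window side length.
#' @param stride step between window origins; defaults to `tile`
#'   (non-overlapping).
#' @return An object of class `tile_grid` with fields `source_size`, `tile`,
#'   `stride`, `padded_size`, `pad` (bottom, right) and `origins`
#'   (n x 2 matrix of 0-based (y, x)).
#' @export
tile_grid <- function(source_size, tile = 256L, stride = tile) {
  source_size <- as.integer(source_size)
  tile <- as.integer(tile)
  stride <- as.integer(stride)
  if (any(source_size < 1L)) stop("empty source")
  if (any(source_size < tile))
    stop("source ", paste(source_size, collapse = "x"),
         " is smaller than one ", tile, "x", tile, " tile")
  if (stride < 1L || stride > tile) stop("stride must be in [1, tile]")
  n_steps <- pmax(0L, as.integer(ceiling((source_size - tile) / stride)))
  padded <- tile + n_steps * stride
  ys <- seq(0L, padded[1L] - tile, by = stride)
  xs <- seq(0L, padded[2L] - tile, by = stride)
  origins <- cbind(y = rep(ys, each = length(xs)), x = rep(xs, length(ys)))
  structure(
    list(source_size = source_size, tile = tile, stride = stride,
         padded_size = padded, pad = padded - source_size, origins = origins),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile grid: %dx%d source, %d tiles of %d (stride %d, pad %d,%d)\n",
              x$source_size[1L], x$source_size[2L], nrow(x$origins), x$tile,
              x$stride, x$pad[1L], x$pad[2L]))
  invisible(x)
}

# reflect-pad an image (matrix or H x W x C array) at bottom/right
pad_reflect <- function(img, bottom, right) {
  if (bottom == 0L && right == 0L) return(img)
  d <- dim(img)
  H <- d[1L]; W <- d[2L]
  ri <- if (bottom > 0L) c(seq_len(H), seq(H - 1L, by = -1L, length.out = bottom)) else seq_len(H)
  ci <- if (right > 0L) c(seq_len(W), seq(W - 1L, by = -1L, length.out = right)) else seq_len(W)
  if (length(d) == 2L) img[ri, ci, drop = FALSE] else img[ri, ci, , drop = FALSE]
}

crop_to <- function(img, size) {
  if (is.null(dim(img)) || length(dim(img)) == 2L)
    img[seq_len(size[1L]), seq_len(size[2L]), drop = FALSE]
  else img[seq_len(size[1L]), seq_len(size[2L]), , drop = FALSE]
}

take_tile <- function(img, oy, ox, tile) {
  ri <- (oy + 1L):(oy + tile)
  ci <- (ox + 1L):(ox + tile)
  if (length(dim(img)) == 2L) img[ri, ci, drop = FALSE]
  else img[ri, ci, , drop = FALSE]
}

#' Split a region into fixed-size tiles
#'
#' Large regions (e.g. 1024 x 1024 crops of a slide) are divided into
#' `tile` x `tile` images for patch-level inference; a 1024 region yields
#' exactly 16 non-overlapping 256 tiles. Non-divisible sizes are
#' reflect-padded bottom/right; [unpatchify()] crops the padding back off,
#' making the round trip lossless.
#'
#' @param region image (H x W matrix or H x W x C array).
#' @param tile tile side length.
#' @param stride grid stride, defaults to `tile`.
#' @return list with the `tile_grid` (`grid`) and the list of `tiles`.
#' @export
patchify <- function(region, tile = 256L, stride = tile) {
  if (is.null(dim(region)) || prod(dim(region)) == 0L) stop("empty image")
  grid <- tile_grid(dim(region)[1:2], tile = tile, stride = stride)
  padded <- pad_reflect(region, grid$pad[1L], grid$pad[2L])
  tiles <- lapply(seq_len(nrow(grid$origins)), function(i)
    take_tile(padded, grid$origins[i, 1L], grid$origins[i, 2L], grid$tile))
  list(grid = grid, tiles = tiles)
}

#' Reassemble tiles into the full-size source
#'
#' Inverse of [patchify()]: with `stride == tile` tile contents are copied
#' straight back (bit-exact round trip); with overlapping grids the
#' overlapping predictions are averaged and, for 2-d mask/probability tiles,
#' thresholded at 0.5.
#'
#' @param grid a `tile_grid`.
#' @param tiles list of tiles matching `grid$origins` (all 2-d, or all 3-d).
#' @param binarize threshold averaged 2-d tiles at 0.5. Defaults to `TRUE`
#'   for overlapping 2-d grids, `FALSE` otherwise.
#' @return The reassembled image cropped to `grid$source_size`.
#' @export
unpatchify <- function(grid, tiles, binarize = NULL) {
  stopifnot(inherits(grid, "tile_grid"))
  if (length(tiles) != nrow(grid$origins))
    stop("expected ", nrow(grid$origins), " tiles, got ", length(tiles),
         " (one per grid origin)")
  d1 <- dim(tiles[[1L]])
  spatial <- c(grid$padded_size[1L], grid$padded_size[2L])
  three_d <- length(d1) == 3L
  if (is.null(binarize)) binarize <- !three_d && grid$stride < grid$tile
  full_dim <- if (three_d) c(spatial, d1[3L]) else spatial
  acc <- array(0, full_dim)
  wt <- array(0, spatial)
  tl <- grid$tile
  for (i in seq_len(nrow(grid$origins))) {
    ri <- (grid$origins[i, 1L] + 1L):(grid$origins[i, 1L] + tl)
    ci <- (grid$origins[i, 2L] + 1L):(grid$origins[i, 2L] + tl)
    if (three_d) acc[ri, ci, ] <- acc[ri, ci, , drop = FALSE] + tiles[[i]]
    else acc[ri, ci] <- acc[ri, ci, drop = FALSE] + tiles[[i]]
    wt[ri, ci] <- wt[ri, ci] + 1
  }
  if (grid$stride == grid$tile) {
    out <- acc   # weights are exactly 1 everywhere
  } else if (three_d) {
    out <- acc / as.vector(wt)
  } else {
    out <- acc / wt
  }
  out <- crop_to(out, grid$source_size)
  if (binarize) out <- (out >= 0.5) * 1L
  out
}

#' Mine training patches from an annotated region of interest
#'
#' Slides a `tile` window at `stride` (default half-overlap) over the ROI
#' and keeps the patches that contain tumor surface: at least
#' `min_positive` positive mask pixels (default 1). Mining is deterministic;
#' patch origins come from the ROI's [tile_grid()].
#'
#' @param roi list with `image` (H x W x C) and `mask` (H x W binary), e.g.
#'   a [generate_roi()] record.
#' @param tile patch side length.
#' @param stride grid stride; defaults to `tile / 2` (half overlap).
#' @param min_positive minimum count of positive mask pixels to keep a patch.
#' @return list of patches, each with `image`, `mask` and 0-based `origin`.
#' @export
mine_training_patches <- function(roi, tile = 256L, stride = tile %/% 2L,
                                  min_positive = 1L) {
  stopifnot(is.list(roi), !is.null(roi$image), !is.null(roi$mask))
  grid <- tile_grid(dim(roi$mask), tile = tile, stride = stride)
  img <- pad_reflect(roi$image, grid$pad[1L], grid$pad[2L])
  msk <- pad_reflect(roi$mask, grid$pad[1L], grid$pad[2L])
  out <- list()
  for (i in seq_len(nrow(grid$origins))) {
    m <- take_tile(msk, grid$origins[i, 1L], grid$origins[i, 2L], grid$tile)
    if (sum(m) >= min_positive) {
      out[[length(out) + 1L]] <- list(
        image = take_tile(img, grid$origins[i, 1L], grid$origins[i, 2L], grid$tile),
        mask = m,
        origin = grid$origins[i, ]
      )
    }
  }
  out
}

#' Tint the positive region of an image
#'
#' Alpha-blends the segmentation color onto the positive mask pixels;
#' negative pixels are returned byte-identical.
#'
#' @param image H x W x 3 RGB array, values in \[0, 1\].
#' @param mask binary mask of matching spatial shape.
#' @param alpha blend weight in \[0, 1\]; 0 returns the image unchanged.
#' @param color tint as RGB in \[0, 1\]; default deep blue.
#' @return The blended RGB array.
#' @export
overlay <- function(image, mask, alpha = 0.4, color = c(0, 0, 1)) {
  d <- dim(image)
  if (length(d) != 3L || !identical(d[1:2], dim2(mask)[1:2]))
    stop("image and mask shapes do not match")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  check_binary(mask, "mask")
  out <- image
  pos <- as.logical(mask)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[pos] <- (1 - alpha) * plane[pos] + alpha * color[ch]
    out[, , ch] <- plane
  }
  out
}
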