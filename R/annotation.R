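# Contour annotations: polygon rasterization into binary masks, the
# deep-blue/black mask color coding, and the four-color difference maps
# used to compare predictions against ground truth.

#' Segmentation color conventions
#'
#' Named RGB colors (0-1 scale): positive tumor regions are deep blue on
#' black background in ground-truth masks; difference maps use light blue
#' for true positives, deep blue for false negatives, gray for false
#' positives and black for true negatives.
#' @export
seg_colors <- function() {
  list(
    deep_blue = c(0, 0, 255) / 255,
    light_blue = c(128, 200, 255) / 255,
    gray = c(128, 128, 128) / 255,
    black = c(0, 0, 0)
  )
}

#' Even-odd point-in-polygon test
#'
#' Vectorized ray-casting: counts crossings of the horizontal ray from each
#' query point; a point is inside when the count is odd. Points exactly on
#' a horizontal edge follow the half-open vertex rule, making adjacent
#' polygons non-overlapping.
#'
#' @param px,py numeric vectors of query coordinates.
#' @param poly n x 2 matrix of polygon vertices (x, y), implicitly closed.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize contour annotations into a binary mask
#'
#' A pixel is positive iff its center lies inside at least one annotated
#' polygon (even-odd rule). Coordinates are 0-based with x growing right
#' and y growing down; pixel (row r, col c) has center (c + 0.5, r + 0.5).
#' The mask is cropped to the half-open bounding box `bbox`.
#'
#' @param annotations list of annotations, each a list with `polygon`
#'   (n x 2 matrix of (x, y) vertices in source-image pixels) and
#'   optionally `label`.
#' @param bbox (x_min, y_min, width, height), 0-based half-open.
#' @return binary mask of dim (height, width).
#' @export
rasterize_mask <- function(annotations, bbox) {
  bbox <- as.numeric(bbox)
  w <- as.integer(bbox[3L]); h <- as.integer(bbox[4L])
  stopifnot(w >= 1L, h >= 1L)
  mask <- matrix(0L, h, w)
  cx <- bbox[1L] + (seq_len(w) - 0.5)   # pixel-center x per column
  cy <- bbox[2L] + (seq_len(h) - 0.5)
  px <- rep(cx, each = h)
  py <- rep(cy, w)
  for (ann in annotations) {
    poly <- ann$polygon
    if (is.null(poly) || nrow(poly) < 3L || polygon_area(poly) == 0) {
      warning("skipping degenerate polygon (fewer than 3 vertices or zero area)")
      next
    }
    inside <- point_in_polygon(px, py, poly)
    mask[inside] <- 1L
  }
  mask
}

polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- nrow(poly)
  abs(sum(x * y[c(2:n, 1L)] - x[c(2:n, 1L)] * y)) / 2
}

#' Encode a binary mask as a ground-truth RGB image
#'
#' Positive pixels become deep blue, negative pixels black.
#' @param mask binary matrix.
#' @return H x W x 3 RGB array in \[0, 1\].
#' @seealso [decode_mask_rgb()] for the inverse.
#' @export
encode_mask_rgb <- function(mask) {
  check_binary(mask, "mask")
  cols <- seg_colors()
  d <- dim(mask)
  out <- array(0, c(d, 3L))
  for (ch in 1:3) out[, , ch] <- mask * cols$deep_blue[ch]
  out
}

#' @rdname encode_mask_rgb
#' @param rgb an image produced by [encode_mask_rgb()].
#' @return the binary mask.
#' @export
decode_mask_rgb <- function(rgb) {
  (rgb[, , 3L] > 0.5) * 1L
}

#' Difference map between ground truth and prediction
#'
#' Renders the four pixel classes with the segmentation colors: the
#' intersection of the masks (true positives) light blue, missed tumor
#' (false negatives) deep blue, spurious predictions (false positives)
#' gray, and agreement on background black. Every pixel receives exactly
#' one color, so the per-color tallies equal [confusion_counts()].
#'
#' @param truth,pred binary masks of equal shape.
#' @return H x W x 3 RGB array in \[0, 1\].
#' @export
difference_map <- function(truth, pred) {
  check_binary(truth, "truth")
  check_binary(pred, "pred")
  if (!identical(dim2(truth), dim2(pred)))
    stop("truth and pred have different shapes")
  cols <- seg_colors()
  t <- as.logical(truth); p <- as.logical(pred)
  d <- dim(truth)
  out <- array(0, c(d, 3L))
  for (ch in 1:3) {
    plane <- matrix(cols$black[ch], d[1L], d[2L])
    plane[p & t] <- cols$light_blue[ch]
    plane[!p & t] <- cols$deep_blue[ch]
    plane[p & !t] <- cols$gray[ch]
    out[, , ch] <- plane
  }
  out
}

#' Read / write polygon annotations as JSON
#'
#' Annotations are stored as a JSON array of objects with a `label` and a
#' `polygon` given as an array of (x, y) vertex pairs.
#'
#' @param path JSON file path.
#' @return `read_annotations()`: list of annotations with `polygon`
#'   matrices; `write_annotations()`: `path`, invisibly.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) {
    lapply(seq_len(nrow(raw)), function(i)
      list(label = raw$label[i],
           polygon = matrix(unlist(raw$polygon[[i]]), ncol = 2L,
                            dimnames = list(NULL, c("x", "y")))))
  } else {
    lapply(raw, function(a)
      list(label = a$label,
           polygon = matrix(unlist(a$polygon), ncol = 2L,
                            dimnames = list(NULL, c("x", "y")))))
  }
}

#' @rdname read_annotations
#' @param annotations list of annotations (`polygon`, `label`).
#' @export
write_annotations <- function(annotations, path) {
  payload <- lapply(annotations, function(a) list(
    label = a$label %||% "positive",
    polygon = unname(apply(a$polygon, 1L, function(v) c(v[1L], v[2L]),
                           simplify = FALSE))
  ))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
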