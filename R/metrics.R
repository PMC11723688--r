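# Overlap metrics: pixel confusion counts, Dice, soft-Dice loss, IoU and
# their dataset-level means.

#' Pixel confusion counts between a predicted and a ground-truth mask
#'
#' @param pred,truth binary masks (0/1 matrices or logical) of equal shape.
#' @return An object of class `confusion_counts` with integer fields
#'   `TP`, `FP`, `FN`, `TN` summing to the number of evaluated pixels.
#' @export
confusion_counts <- function(pred, truth) {
  check_binary(pred, "pred")
  check_binary(truth, "truth")
  if (!identical(dim2(pred), dim2(truth)))
    stop("pred and truth have different shapes")
  p <- as.logical(pred)
  t <- as.logical(truth)
  structure(
    list(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t),
         TN = sum(!p & !t)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

check_binary <- function(m, what) {
  v <- as.vector(m)
  if (is.logical(v)) return(invisible(TRUE))
  if (!all(v %in% c(0, 1)))
    stop(what, " must be a binary (0/1) mask")
  invisible(TRUE)
}

dim2 <- function(m) if (is.null(dim(m))) length(m) else dim(m)

#' Dice similarity coefficient
#'
#' `Dice = 2 TP / (2 TP + FP + FN)`. Two empty masks (TP = FP = FN = 0) are
#' in perfect agreement and score 1.
#'
#' @param x a `confusion_counts` object, or a binary predicted mask (then
#'   `truth` must be given).
#' @param truth binary ground-truth mask when `x` is a mask.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(x, truth = NULL) {
  if (!inherits(x, "confusion_counts")) x <- confusion_counts(x, truth)
  den <- 2 * x$TP + x$FP + x$FN
  if (den == 0) return(1)
  2 * x$TP / den
}

#' Intersection over union (Jaccard index)
#'
#' `IoU = |pred & truth| / |pred | truth|`; two empty masks score 1.
#' Related to Dice by `Dice = 2 IoU / (1 + IoU)`.
#'
#' @param pred,truth binary masks of equal shape.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  den <- cc$TP + cc$FP + cc$FN
  if (den == 0) return(1)
  cc$TP / den
}

#' Soft Dice loss
#'
#' `1 - Dice` evaluated on probabilities: the counts of the Dice coefficient
#' are replaced with sums of products over the predicted foreground
#' probabilities, making the loss differentiable. A smoothing term
#' `eps` added to numerator and denominator stabilizes the empty-mask case.
#' On binary predictions the loss reduces to `1 - dice(...)` up to the
#' smoothing term.
#'
#' @param pred foreground probability map, values in \[0, 1\].
#' @param truth binary mask of the same shape.
#' @param eps smoothing term (default 1).
#' @return Loss in \[0, 1\].
#' @seealso [dice_loss_grad()] for the analytic gradient.
#' @export
dice_loss <- function(pred, truth, eps = 1) {
  if (!identical(dim2(pred), dim2(truth)))
    stop("pred and truth have different shapes")
  if (any(pred < 0 | pred > 1)) stop("pred values must lie in [0, 1]")
  check_binary(truth, "truth")
  i <- sum(pred * truth)
  s <- sum(pred) + sum(truth)
  1 - (2 * i + eps) / (s + eps)
}

#' Analytic gradient of the soft Dice loss with respect to the prediction
#'
#' @inheritParams dice_loss
#' @return Array of the same shape as `pred`.
#' @export
dice_loss_grad <- function(pred, truth, eps = 1) {
  i <- sum(pred * truth)
  s <- sum(pred) + sum(truth)
  g <- -(2 * truth * (s + eps) - (2 * i + eps)) / (s + eps)^2
  if (!is.null(dim(pred))) dim(g) <- dim(pred)
  g
}

#' Dataset-level metric means
#'
#' Unweighted per-image means: `accuracy` is the mean Dice coefficient
#' expressed in percent, `mean_iou` the mean IoU.
#'
#' @param per_image a data.frame (or list of lists) with columns/fields
#'   `dice` and `iou`, one row per evaluated image.
#' @return list with `accuracy_percent` and `mean_iou`.
#' @export
aggregate_metrics <- function(per_image) {
  if (is.data.frame(per_image)) {
    d <- per_image$dice
    j <- per_image$iou
  } else {
    d <- vapply(per_image, `[[`, 0, "dice")
    j <- vapply(per_image, `[[`, 0, "iou")
  }
  if (length(d) == 0L) stop("no per-image metrics to aggregate")
  list(accuracy_percent = 100 * mean(d), mean_iou = mean(j))
}

#' Write a benchmark metrics report
#'
#' One row per model: accuracy (mean Dice, percent), mean IoU, parameter
#' count in millions, and the informational (hardware-dependent) timing
#' columns.
#'
#' @param rows data.frame with columns `variant`, `accuracy`, `mean_iou`,
#'   `params_millions` and optionally `epoch_train_time_s`, `eval_time_ms`.
#' @param path optional CSV path; written with [utils::write.csv()].
#' @return The report data.frame, invisibly if written to disk.
#' @export
metrics_report <- function(rows, path = NULL) {
  req <- c("variant", "accuracy", "mean_iou", "params_millions")
  stopifnot(all(req %in% names(rows)))
  bad <- !is.na(rows$accuracy) & (rows$accuracy < 0 | rows$accuracy > 100)
  if (any(bad)) stop("accuracy must lie in [0, 100]")
  badi <- !is.na(rows$mean_iou) & (rows$mean_iou < 0 | rows$mean_iou > 1)
  if (any(badi)) stop("mean_iou must lie in [0, 1]")
  if (!is.null(path)) {
    utils::write.csv(rows, path, row.names = FALSE)
    return(invisible(rows))
  }
  rows
}
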