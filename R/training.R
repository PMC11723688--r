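# Training protocol: soft Dice loss, Adam with default parameters,
# flip-only on-the-fly augmentation, model selection at the epoch with the
# best validation Dice.

#' Training protocol configuration
#'
#' The reference protocol trains for 100 epochs with batches of 16 patches
#' under Adam at its default parameters, minimizing the soft Dice loss,
#' with on-the-fly random horizontal/vertical flips as the only
#' augmentation (flips preserve the histological content of a patch; other
#' transforms would distort it). The checkpoint kept is the epoch with the
#' best validation Dice; validation Dice is computed on binarized (arg-max)
#' predictions, matching evaluation.
#'
#' @param epochs number of training epochs.
#' @param batch_size patches per gradient step.
#' @param lr,beta1,beta2,adam_eps Adam hyperparameters.
#' @param flip_prob per-axis flip probability during augmentation.
#' @param dice_eps soft Dice smoothing term.
#' @param early_stop_dice optional validation Dice at which training stops
#'   early (the protocol default is `NULL`: always run all epochs).
#' @param seed RNG seed governing shuffling and augmentation; recorded in
#'   the run log.
#' @param verbose print per-epoch progress.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 16L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-7,
                         flip_prob = 0.5, dice_eps = 1,
                         early_stop_dice = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1L, batch_size >= 1L)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
         flip_prob = flip_prob, dice_eps = dice_eps,
         early_stop_dice = early_stop_dice, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

#' Random flip augmentation of a patch
#'
#' Applies an identical horizontal and/or vertical flip to the image and its
#' mask (drawn independently with probability `flip_prob` each); no other
#' transform. Flips permute pixels, so mask statistics such as the
#' foreground area are preserved exactly.
#'
#' @param patch list with `image` (H x W x C) and `mask` (H x W).
#' @param flip_prob per-axis flip probability.
#' @return the augmented patch.
#' @export
augment <- function(patch, flip_prob = 0.5) {
  fh <- stats::runif(1) < flip_prob
  fv <- stats::runif(1) < flip_prob
  if (fh) {
    idx <- rev(seq_len(dim(patch$mask)[2L]))
    patch$image <- patch$image[, idx, , drop = FALSE]
    patch$mask <- patch$mask[, idx, drop = FALSE]
  }
  if (fv) {
    idx <- rev(seq_len(dim(patch$mask)[1L]))
    patch$image <- patch$image[idx, , , drop = FALSE]
    patch$mask <- patch$mask[idx, , drop = FALSE]
  }
  patch
}

# mean per-sample soft Dice loss over a batch and its gradient wrt the
# foreground probability plane
batch_dice_loss <- function(probs_fg, masks, eps = 1) {
  d <- dim(probs_fg)               # (H, W, N)
  n <- d[3L]
  grad <- array(0, d)
  loss <- 0
  for (j in seq_len(n)) {
    p <- probs_fg[, , j]
    t <- masks[, , j]
    i <- sum(p * t)
    s <- sum(p) + sum(t)
    loss <- loss + 1 - (2 * i + eps) / (s + eps)
    grad[, , j] <- -(2 * t * (s + eps) - (2 * i + eps)) / ((s + eps)^2 * n)
  }
  list(loss = loss / n, grad = grad)
}

#' Train a segmentation network
#'
#' Runs the Dice-loss protocol of [train_config()] on paired image/mask
#' patches, evaluating the validation split after every epoch and keeping a
#' checkpoint of the best-validation-Dice epoch (ties broken by the
#' earliest epoch). Training is deterministic given the seed.
#'
#' @param net a [unet()] network.
#' @param train_set,val_set lists of patches (`image`, `mask`) whose spatial
#'   size matches the network input.
#' @param config a [train_config()].
#' @return An object of class `unet_fit`: the trained network, the per-epoch
#'   `log` (`train_loss`, `val_dice`, `val_iou`, `val_soft_dice`),
#'   `best_epoch`, and the best checkpoint.
#' @export
unet_train <- function(net, train_set, val_set, config = train_config()) {
  stopifnot(inherits(net, "unet"), inherits(config, "train_config"))
  if (length(train_set) == 0L) stop("empty training set")
  if (length(val_set) == 0L) stop("empty validation set")
  check_patch_shapes(net, train_set[[1L]])
  set.seed(config$seed)
  opt <- adam_init(net$params)
  n <- length(train_set)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_dice = numeric(), val_iou = numeric(),
                    val_soft_dice = numeric())
  best <- list(epoch = 0L, val_dice = -Inf, params = NULL, state = NULL)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    n_batches <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(i + config$batch_size - 1L, n)
      batch <- lapply(train_set[ord[i:j]], augment,
                      flip_prob = config$flip_prob)
      x <- stack_patches(lapply(batch, `[[`, "image"))
      masks <- array(0, c(dim(batch[[1L]]$mask), length(batch)))
      for (k in seq_along(batch)) masks[, , k] <- batch[[k]]$mask
      fwd <- net_forward(net, x, training = TRUE)
      net$state <- fwd$state
      probs <- fwd$out
      fg <- probs[, , , 2L]
      dim(fg) <- dim(probs)[1:3]
      dl <- batch_dice_loss(fg, masks, eps = config$dice_eps)
      if (!is.finite(dl$loss))
        stop("non-finite Dice loss at epoch ", epoch,
             "; try a lower learning rate or a different initialization seed")
      dprobs <- array(0, dim(probs))
      dprobs[, , , 2L] <- dl$grad
      grads <- net_backward(net, fwd, dprobs)
      stepped <- adam_step(net$params, grads, opt, lr = config$lr,
                           beta1 = config$beta1, beta2 = config$beta2,
                           eps = config$adam_eps)
      net$params <- stepped$params
      opt <- stepped$opt
      ep_loss <- ep_loss + dl$loss
      n_batches <- n_batches + 1L
      i <- j + 1L
    }
    val <- evaluate_patches(net, val_set, soft = TRUE,
                            eps = config$dice_eps)
    log <- rbind(log, data.frame(
      epoch = epoch, train_loss = ep_loss / n_batches,
      val_dice = val$accuracy_percent / 100, val_iou = val$mean_iou,
      val_soft_dice = val$soft_dice
    ))
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  val dice %.4f", epoch,
                      log$train_loss[epoch], log$val_dice[epoch]))
    if (log$val_dice[epoch] > best$val_dice) {
      best <- list(epoch = epoch, val_dice = log$val_dice[epoch],
                   params = net$params, state = net$state)
    }
    if (!is.null(config$early_stop_dice) &&
        log$val_dice[epoch] >= config$early_stop_dice) break
  }
  structure(
    list(net = net, log = log, best_epoch = best$epoch,
         best_params = best$params, best_state = best$state,
         config = config),
    class = "unet_fit"
  )
}

check_patch_shapes <- function(net, patch) {
  cfg <- net$config
  d <- dim(patch$image)
  if (d[1L] != cfg$input_size[1L] || d[2L] != cfg$input_size[2L] ||
      d[3L] != cfg$channels)
    stop("patch shape ", paste(d, collapse = "x"),
         " does not match the network input ",
         paste(c(cfg$input_size, cfg$channels), collapse = "x"))
  invisible(TRUE)
}

# evaluate a patch set: binarized per-patch Dice/IoU means (and optionally
# the mean soft Dice for the log)
evaluate_patches <- function(net, patches, soft = FALSE, eps = 1,
                             batch_size = 16L) {
  if (inherits(net, "unet_fit")) net <- best_network(net)
  probs <- predict_batch(net, lapply(patches, `[[`, "image"),
                         type = "prob", batch_size = batch_size)
  ds <- numeric(length(patches))
  js <- numeric(length(patches))
  sds <- numeric(length(patches))
  for (k in seq_along(patches)) {
    pm <- (probs[[k]][, , 2L] >= probs[[k]][, , 1L]) * 1L
    tm <- patches[[k]]$mask
    ds[k] <- dice(pm, tm)
    js[k] <- iou(pm, tm)
    if (soft) sds[k] <- 1 - dice_loss(probs[[k]][, , 2L], tm, eps = eps)
  }
  out <- aggregate_metrics(data.frame(dice = ds, iou = js))
  if (soft) out$soft_dice <- mean(sds)
  out$per_image <- data.frame(dice = ds, iou = js)
  out
}

#' Best checkpoint of a training run
#'
#' `select_best()` returns the index of the epoch with the highest
#' validation Dice (earliest epoch on ties); `best_network()` returns the
#' network with the parameters and batch-norm state of that checkpoint.
#'
#' @param log a training log data.frame with a `val_dice` column, or a
#'   `unet_fit`.
#' @return `select_best()`: the epoch index.
#' @export
select_best <- function(log) {
  if (inherits(log, "unet_fit")) log <- log$log
  if (nrow(log) == 0L) stop("empty training log")
  which.max(log$val_dice)
}

#' @rdname select_best
#' @param fit a [unet_train()] result.
#' @export
best_network <- function(fit) {
  stopifnot(inherits(fit, "unet_fit"))
  set_params(fit$net, fit$best_params, fit$best_state)
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit> %s variant, %d epoch(s)\n", x$net$variant,
              nrow(x$log)))
  cat(sprintf("  best epoch %d: validation Dice %.4f, IoU %.4f\n",
              x$best_epoch, x$log$val_dice[x$best_epoch],
              x$log$val_iou[x$best_epoch]))
  invisible(x)
}

#' @export
summary.unet_fit <- function(object, ...) {
  cat(sprintf("%s U-Net fit (seed %d)\n", object$net$variant,
              object$config$seed))
  print(object$log, row.names = FALSE)
  cat(sprintf("best epoch: %d (validation Dice %.4f)\n", object$best_epoch,
              object$log$val_dice[object$best_epoch]))
  invisible(object)
}

#' @export
predict.unet_fit <- function(object, newdata, type = c("prob", "mask"), ...) {
  predict_batch(best_network(object), newdata, type = match.arg(type))
}

#' @export
plot.unet_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$log$epoch, x$log$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training Dice loss", ...)
  graphics::plot(x$log$epoch, x$log$val_dice, type = "b", pch = 16,
                 xlab = "epoch", ylab = "validation Dice", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Save / restore a fit checkpoint
#'
#' Checkpoints serialize the best parameters, batch-norm state and log so a
#' reloaded fit reproduces its validation metrics exactly.
#'
#' @param fit a `unet_fit`.
#' @param path file path (RDS).
#' @return `load_checkpoint()` returns the restored `unet_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "unet_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "unet_fit"))
  fit
}
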