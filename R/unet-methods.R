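# S3 surface of the network objects.

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<unet> %s variant\n", x$variant))
  cat(sprintf("  input %dx%dx%d, depth %d, base filters %d, %d conv(s)/block\n",
              cfg$input_size[1L], cfg$input_size[2L], cfg$channels,
              cfg$depth, cfg$base_filters, cfg$convs_per_block))
  cat(sprintf("  trainable parameters: %s (%.2f x 10^6)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

#' @export
summary.unet <- function(object, ...) {
  ops <- vapply(object$nodes, function(nd) nd$op, "")
  by_op <- table(ops)
  n_par <- count_parameters(object)
  out <- list(variant = object$variant, nodes = length(object$nodes),
              ops = by_op, parameters = n_par,
              parameters_millions = round(n_par / 1e6, 2))
  class(out) <- "summary.unet"
  out
}

#' @export
print.summary.unet <- function(x, ...) {
  cat(sprintf("%s U-Net: %d graph nodes, %s trainable parameters (%.2f x 10^6)\n",
              x$variant, x$nodes, format(x$parameters, big.mark = ","),
              x$parameters_millions))
  print(x$ops)
  invisible(x)
}

# Stack a list of H x W x C image arrays into the engine's (H, W, N, C) layout.
stack_patches <- function(patches) {
  if (is.array(patches) && length(dim(patches)) == 3L) patches <- list(patches)
  d <- dim(patches[[1L]])
  x <- array(0, c(d[1L], d[2L], length(patches), d[3L]))
  for (n in seq_along(patches)) x[, , n, ] <- patches[[n]]
  x
}

#' Per-pixel class probabilities for a batch of patches
#'
#' Runs the network forward in evaluation mode (batch-norm running
#' statistics). The output softmax guarantees the class probabilities sum to
#' one at every pixel; a binary mask is obtained by arg-max, i.e. foreground
#' probability >= 0.5.
#'
#' @param net a [unet()] network or [unet_train()] fit (the best checkpoint
#'   is used).
#' @param patches one H x W x C array, or a list of them.
#' @param type `"prob"` for H x W x out_channels probability maps, `"mask"`
#'   for binary foreground masks.
#' @param batch_size forward micro-batch size.
#' @return A single map/mask if one patch was given, else a list.
#' @export
predict_batch <- function(net, patches, type = c("prob", "mask"),
                          batch_size = 16L) {
  type <- match.arg(type)
  if (inherits(net, "unet_fit")) net <- best_network(net)
  stopifnot(inherits(net, "unet"))
  single <- is.array(patches) && length(dim(patches)) == 3L
  if (single) patches <- list(patches)
  cfg <- net$config
  for (p in patches) {
    d <- dim(p)
    if (length(d) != 3L || d[1L] != cfg$input_size[1L] ||
        d[2L] != cfg$input_size[2L] || d[3L] != cfg$channels)
      stop("patch shape ", paste(d, collapse = "x"),
           " does not match the network input ",
           paste(c(cfg$input_size, cfg$channels), collapse = "x"))
  }
  res <- vector("list", length(patches))
  i <- 1L
  while (i <= length(patches)) {
    j <- min(i + batch_size - 1L, length(patches))
    x <- stack_patches(patches[i:j])
    pr <- net_forward(net, x, training = FALSE, keep_cache = FALSE)$out
    for (n in seq_len(j - i + 1L)) {
      m <- pr[, , n, ]
      res[[i + n - 1L]] <- if (type == "prob") m else
        (m[, , 2L] >= m[, , 1L]) * 1L
    }
    i <- j + 1L
  }
  if (single) res[[1L]] else res
}

#' @rdname predict_batch
#' @param object,newdata,... standard predict arguments; `newdata` as
#'   `patches` above.
#' @export
predict.unet <- function(object, newdata, type = c("prob", "mask"), ...) {
  predict_batch(object, newdata, type = match.arg(type))
}

set_params <- function(net, params, state = NULL) {
  net$params <- params
  if (!is.null(state)) net$state <- state
  net
}
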