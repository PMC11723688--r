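#' Unified backbone configuration for all U-Net variants
#'
#' Every architecture in [unet_variants()] is instantiated from this single
#' configuration: an encoder-decoder with `depth` max-pooling/upsampling
#' stages, `base_filters` channels at the first stage doubling after each
#' pooling (and halving at each upsampling), `convs_per_block` 3x3
#' convolutions per stage, each convolution followed by batch normalization
#' and a ReLU, 2x2 max pooling for downsampling, 2x2 stride-2 transposed
#' convolutions for upsampling, and a 1x1 output convolution with a softmax
#' over `out_channels` per-pixel classes (foreground tumor vs background).
#'
#' @param input_size integer vector of length 2, spatial size (rows, cols) of
#'   input patches. Must be divisible by `2^depth`.
#' @param channels number of input image channels (3 for RGB histology).
#' @param depth number of pooling/upsampling stages.
#' @param base_filters channel count of the first stage.
#' @param convs_per_block number of convolutions per encoder/decoder stage.
#' @param out_channels number of output classes (2: tumor / background).
#' @param bn_momentum decay of the batch-norm running statistics.
#' @param bn_eps batch-norm variance floor.
#' @param block_params named list of per-variant knobs; see Details.
#'
#' @details `block_params` holds the variant-specific design knobs, each
#' pinned so the built network's trainable-parameter count reproduces the
#' published complexity column for that variant:
#' \describe{
#'   \item{attention_width}{attention-gate intermediate channels as a
#'     multiple of the skip's channels (default 1).}
#'   \item{se_reduction}{squeeze-and-excitation bottleneck reduction ratio
#'     (default 2).}
#'   \item{dense_growth}{dense-block growth rate as a fraction of the stage
#'     width (default 15/16).}
#'   \item{inception_reduce}{width of the 1x1 reduction convolutions feeding
#'     the 3x3 and 5x5 inception branches, as a multiple of the stage width
#'     (default 5/4).}
#'   \item{unetpp_node_convs}{convolutions per U-Net++ node (default 2; the
#'     node that first refines the bottleneck keeps `convs_per_block`).}
#' }
#'
#' @return An object of class `unet_config`.
#' @seealso [unet()], [count_parameters()]
#' @export
unet_config <- function(input_size = c(256L, 256L), channels = 3L, depth = 4L,
                        base_filters = 16L, convs_per_block = 3L,
                        out_channels = 2L, bn_momentum = 0.9, bn_eps = 1e-3,
                        block_params = list()) {
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  bp <- utils::modifyList(
    list(attention_width = 1, se_reduction = 2, dense_growth = 15 / 16,
         inception_reduce = 5 / 4, unetpp_node_convs = 2L),
    block_params
  )
  cfg <- structure(
    list(input_size = as.integer(input_size), channels = as.integer(channels),
         depth = as.integer(depth), base_filters = as.integer(base_filters),
         convs_per_block = as.integer(convs_per_block),
         out_channels = as.integer(out_channels),
         bn_momentum = bn_momentum, bn_eps = bn_eps, block_params = bp),
    class = "unet_config"
  )
  if (cfg$depth < 1L || cfg$base_filters < 1L || cfg$convs_per_block < 1L)
    stop("depth, base_filters and convs_per_block must all be >= 1")
  if (any(cfg$input_size %% 2L^cfg$depth != 0L))
    stop("input_size ", paste(cfg$input_size, collapse = "x"),
         " is not divisible by 2^depth = ", 2L^cfg$depth,
         "; pooling would truncate the feature maps")
  cfg
}

#' Names of the implemented U-Net architecture variants
#' @return Character vector of the seven variant identifiers.
#' @export
unet_variants <- function() {
  c("vanilla", "attention", "residual", "dense", "inception", "se", "unetpp")
}

#' Build a U-Net architecture variant
#'
#' Constructs a trainable encoder-decoder segmentation network from the
#' unified backbone configuration. The seven variants differ only in their
#' block internals: plain stacked convolutions (`vanilla`), additive
#' attention gates on the skip connections (`attention`), identity residual
#' shortcuts inside each block (`residual`), densely connected blocks with a
#' 1x1 transition (`dense`), parallel 1x1/3x3/5x5/max-pool branches
#' (`inception`), channel recalibration after each block (`se`), and nested
#' dense skip pathways (`unetpp`).
#'
#' @param variant one of [unet_variants()].
#' @param config a [unet_config()].
#' @param seed integer seed for weight initialization (He fan-in scaling).
#' @return An object of class `unet` holding the computation graph, its
#'   parameters and batch-norm state.
#' @examples
#' net <- unet("vanilla", unet_config(input_size = 32, depth = 2,
#'                                    base_filters = 4))
#' count_parameters(net)
#' @export
unet <- function(variant, config = unet_config(), seed = 1L) {
  if (length(variant) != 1L || !variant %in% unet_variants())
    stop("unknown variant ", deparse(variant), "; must be one of: ",
         paste(unet_variants(), collapse = ", "))
  stopifnot(inherits(config, "unet_config"))
  set.seed(seed)
  gb <- new_graph(config$channels)
  builder <- switch(variant,
    vanilla = build_vanilla, attention = build_attention,
    residual = build_residual, dense = build_dense,
    inception = build_inception, se = build_se, unetpp = build_unetpp
  )
  out_id <- builder(gb, config)
  structure(
    list(variant = variant, config = config, seed = seed,
         nodes = gb$nodes, params = gb$params, state = gb$state,
         output_id = out_id),
    class = "unet"
  )
}

#' Count the trainable parameters of a network
#'
#' Sums every trainable scalar: convolution and transposed-convolution
#' weights and biases, and batch-normalization scale/shift pairs. Running
#' batch-norm statistics are not trainable and are excluded.
#'
#' @param net a [unet()] network or a [unet_train()] fit.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  if (inherits(net, "unet_fit")) net <- net$net
  stopifnot(inherits(net, "unet"))
  sum(vapply(net$params, length, 1L))
}

# ---- shared block helpers -------------------------------------------------

cbr <- function(gb, x, f, cfg, k = 3L) {
  x <- g_conv(gb, x, f, k = k)
  x <- g_bn(gb, x, momentum = cfg$bn_momentum, eps = cfg$bn_eps)
  g_relu(gb, x)
}

plain_block <- function(gb, x, f, cfg, n = cfg$convs_per_block) {
  for (i in seq_len(n)) x <- cbr(gb, x, f, cfg)
  x
}

stage_filters <- function(cfg) cfg$base_filters * 2L^(0:cfg$depth)

upsample <- function(gb, x, f, cfg) {
  x <- g_convt2(gb, x, f)
  x <- g_bn(gb, x, momentum = cfg$bn_momentum, eps = cfg$bn_eps)
  g_relu(gb, x)
}

output_head <- function(gb, x, cfg) {
  x <- g_conv(gb, x, cfg$out_channels, k = 1L)
  g_softmax(gb, x)
}

# Generic encoder/decoder scaffold: `block(gb, x, f)` builds one stage,
# `post(gb, x, f)` optionally wraps its output (e.g. SE recalibration).
scaffold <- function(gb, cfg, block, post = NULL, skip_hook = NULL) {
  f <- stage_filters(cfg)
  x <- 1L   # input node
  skips <- integer(cfg$depth)
  for (i in seq_len(cfg$depth)) {
    x <- block(gb, x, f[i])
    if (!is.null(post)) x <- post(gb, x, f[i])
    skips[i] <- x
    x <- g_pool2(gb, x)
  }
  x <- block(gb, x, f[cfg$depth + 1L])
  if (!is.null(post)) x <- post(gb, x, f[cfg$depth + 1L])
  for (i in rev(seq_len(cfg$depth))) {
    up <- upsample(gb, x, f[i], cfg)
    sk <- skips[i]
    if (!is.null(skip_hook)) sk <- skip_hook(gb, sk, up, f[i])
    x <- g_concat(gb, c(up, sk))
    x <- block(gb, x, f[i])
    if (!is.null(post)) x <- post(gb, x, f[i])
  }
  output_head(gb, x, cfg)
}

# ---- variants -------------------------------------------------------------

build_vanilla <- function(gb, cfg) {
  scaffold(gb, cfg, function(gb, x, f) plain_block(gb, x, f, cfg))
}

# Residual: the first convolution sets the stage width, then an identity
# shortcut spans the remaining convolutions (pre-activation channels match,
# so no projection parameters are needed; the count stays at the vanilla
# block's, matching the published complexity).
build_residual <- function(gb, cfg) {
  block <- function(gb, x, f) {
    x <- cbr(gb, x, f, cfg)
    if (cfg$convs_per_block == 1L) return(x)
    t <- x
    for (i in seq_len(cfg$convs_per_block - 2L)) t <- cbr(gb, t, f, cfg)
    t <- g_conv(gb, t, f, k = 3L)
    t <- g_bn(gb, t, momentum = cfg$bn_momentum, eps = cfg$bn_eps)
    g_relu(gb, g_addop(gb, t, x))
  }
  scaffold(gb, cfg, block)
}

# Attention: additive gates on each skip connection, gated by the upsampled
# decoder signal at the same resolution. Intermediate width = skip width
# times `attention_width` (default 1, pinned by the published count).
build_attention <- function(gb, cfg) {
  gate <- function(gb, sk, up, f) {
    fint <- max(1L, as.integer(round(cfg$block_params$attention_width * f)))
    qs <- g_conv(gb, sk, fint, k = 1L)
    qg <- g_conv(gb, up, fint, k = 1L)
    q <- g_relu(gb, g_addop(gb, qs, qg))
    psi <- g_sigmoid(gb, g_conv(gb, q, 1L, k = 1L))
    g_scale_spatial(gb, sk, psi)
  }
  scaffold(gb, cfg, function(gb, x, f) plain_block(gb, x, f, cfg),
           skip_hook = gate)
}

# Squeeze-and-excitation: channel recalibration after every stage block,
# bottleneck reduction ratio `se_reduction` (default 2).
build_se <- function(gb, cfg) {
  se <- function(gb, x, f) {
    cr <- max(1L, as.integer(round(f / cfg$block_params$se_reduction)))
    s <- g_gap(gb, x)
    s <- g_relu(gb, g_conv(gb, s, cr, k = 1L))
    s <- g_sigmoid(gb, g_conv(gb, s, f, k = 1L))
    g_scale_channel(gb, x, s)
  }
  scaffold(gb, cfg, function(gb, x, f) plain_block(gb, x, f, cfg), post = se)
}

# Dense: each stage is a densely connected block (every 3x3 convolution sees
# the concatenation of the block input and all previous outputs, growth rate
# `dense_growth * f`) closed by a 1x1 transition to the stage width.
build_dense <- function(gb, cfg) {
  block <- function(gb, x, f) {
    k <- max(1L, as.integer(round(cfg$block_params$dense_growth * f)))
    feats <- x
    for (i in seq_len(cfg$convs_per_block)) {
      y <- cbr(gb, feats, k, cfg)
      feats <- g_concat(gb, c(feats, y))
    }
    cbr(gb, feats, f, cfg, k = 1L)
  }
  scaffold(gb, cfg, block)
}

# Inception: each "convolution" of the block is a four-branch module --
# 1x1, 1x1-reduce + 3x3, 1x1-reduce + 5x5, and 3x3 same max-pool + 1x1 --
# each branch contributing f/4 channels. The reduction width is
# `inception_reduce * f` (default 5/4, pinned by the published count).
build_inception <- function(gb, cfg) {
  imodule <- function(gb, x, f) {
    fb <- f %/% 4L
    stopifnot(fb * 4L == f)
    r <- max(1L, as.integer(round(cfg$block_params$inception_reduce * f)))
    b1 <- cbr(gb, x, fb, cfg, k = 1L)
    b2 <- cbr(gb, cbr(gb, x, r, cfg, k = 1L), fb, cfg, k = 3L)
    b3 <- cbr(gb, cbr(gb, x, r, cfg, k = 1L), fb, cfg, k = 5L)
    b4 <- cbr(gb, g_pool3s1(gb, x), fb, cfg, k = 1L)
    g_concat(gb, c(b1, b2, b3, b4))
  }
  block <- function(gb, x, f) {
    for (i in seq_len(cfg$convs_per_block)) x <- imodule(gb, x, f)
    x
  }
  scaffold(gb, cfg, block)
}

# U-Net++: nested dense skip pathways. All nodes (backbone column included)
# use `unetpp_node_convs` convolutions; the node that first refines the
# bottleneck keeps the backbone's `convs_per_block` (the structural knob
# pinned by the published count). Upsampling halves channels; deep
# supervision is off -- the head reads the top-most node of the last column.
build_unetpp <- function(gb, cfg) {
  f <- stage_filters(cfg)
  d <- cfg$depth
  ncv <- cfg$block_params$unetpp_node_convs
  X <- matrix(NA_integer_, d + 1L, d + 1L)   # X[i+1, j+1] node ids
  x <- 1L
  for (i in 0:d) {
    x <- plain_block(gb, x, f[i + 1L], cfg, n = ncv)
    X[i + 1L, 1L] <- x
    if (i < d) x <- g_pool2(gb, x)
  }
  for (j in 1:d) {
    for (i in 0:(d - j)) {
      up <- upsample(gb, X[i + 2L, j], f[i + 1L], cfg)
      x <- g_concat(gb, c(X[i + 1L, 1:j], up))
      n_here <- if (i == d - 1L && j == 1L) cfg$convs_per_block else ncv
      x <- plain_block(gb, x, f[i + 1L], cfg, n = n_here)
      X[i + 1L, j + 1L] <- x
    }
  }
  output_head(gb, X[1L, d + 1L], cfg)
}
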