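# Independent oracles and fixture builders shared across tests.

# Closed-form parameter count of the vanilla backbone, computed from the
# layer arithmetic alone (k^2*Cin*Cout + Cout per conv, 4*Cin*Cout + Cout
# per 2x2 transposed conv, 2*C per batch norm) -- never touches the
# network builders.
vanilla_param_oracle <- function(base = 16, depth = 4, convs = 3, cin = 3,
                                 out = 2) {
  conv <- function(k, ci, co) k * k * ci * co + co
  bn <- function(c) 2 * c
  block <- function(ci, f) {
    tot <- conv(3, ci, f) + bn(f)
    if (convs > 1) tot <- tot + (convs - 1) * (conv(3, f, f) + bn(f))
    tot
  }
  f <- base * 2^(0:depth)
  tot <- 0
  prev <- cin
  for (i in 1:depth) {
    tot <- tot + block(prev, f[i])
    prev <- f[i]
  }
  tot <- tot + block(prev, f[depth + 1])
  for (i in depth:1) {
    tot <- tot + (4 * f[i + 1] * f[i] + f[i]) + bn(f[i])
    tot <- tot + block(2 * f[i], f[i])
  }
  tot + conv(1, f[1], out)
}

# scalar even-odd ray-casting, written independently of the package's
# vectorized implementation
pip_bruteforce <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > py) != (poly[j, 2] > py)) {
      x_cross <- poly[j, 1] + (py - poly[j, 2]) *
        (poly[i, 1] - poly[j, 1]) / (poly[i, 2] - poly[j, 2])
      if (px < x_cross) inside <- !inside
    }
    j <- i
  }
  inside
}

# star-shaped random simple polygon around a center
random_polygon <- function(cx, cy, r_base, n_vertices = 12) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- r_base * stats::runif(n_vertices, 0.5, 1.3)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

random_mask <- function(h, w, p = 0.5) {
  matrix(stats::rbinom(h * w, 1, p), h, w)
}

# per-pixel color rule: assign tumor where the pixel is closer to the
# configured foreground mean color than to the background mean color
threshold_classifier <- function(image, cfg) {
  d_fg <- (image[, , 1] - cfg$fg_color[1])^2 +
    (image[, , 2] - cfg$fg_color[2])^2 + (image[, , 3] - cfg$fg_color[3])^2
  d_bg <- (image[, , 1] - cfg$bg_color[1])^2 +
    (image[, , 2] - cfg$bg_color[2])^2 + (image[, , 3] - cfg$bg_color[3])^2
  (d_fg < d_bg) * 1L
}

# the desk-scale profile used by the training tests: small separable
# fixtures and a correspondingly small backbone
tiny_fixture_config <- function(seed = 11, n_sources = 6, difficulty = 0) {
  fixture_config(n_sources = n_sources, roi_size = 96, tile = 32,
                 n_blobs = 2, blob_scale = 18, difficulty = difficulty,
                 seed = seed)
}

tiny_net_config <- function() {
  unet_config(input_size = 32, depth = 2, base_filters = 8,
              convs_per_block = 2)
}

tiny_corpus_sets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # learnability keep rule: kept patches carry >= 5% tumor surface
      corpus <- build_corpus(tiny_fixture_config(), n_test = 1, n_val = 1,
                             min_positive = ceiling(0.05 * 32^2))
      cache <<- list(
        train = split_patches(corpus, "train"),
        val = split_patches(corpus, "val"),
        test = split_patches(corpus, "test"),
        corpus = corpus
      )
    }
    cache
  }
})
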