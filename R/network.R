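# Network graph: a topologically ordered DAG of operator nodes over the
# tensor primitives in ops.R. Built once per architecture variant; the same
# structure serves parameter counting, forward prediction and training.

new_graph <- function(in_channels) {
  gb <- new.env(parent = emptyenv())
  gb$nodes <- list()
  gb$params <- list()
  gb$state <- list()
  gb$channels <- integer()   # channel count of each node's output
  gb$level <- integer()      # spatial downsampling level (0 = input resolution)
  g_add(gb, list(op = "input"), channels = in_channels, level = 0L)
  gb
}

g_add <- function(gb, node, channels, level) {
  id <- length(gb$nodes) + 1L
  gb$nodes[[id]] <- node
  gb$channels[id] <- channels
  gb$level[id] <- level
  id
}

g_param <- function(gb, name, value) {
  stopifnot(is.null(gb$params[[name]]))
  gb$params[[name]] <- value
  name
}

# -- node constructors ------------------------------------------------------

g_conv <- function(gb, input, cout, k = 3L, tag = NULL) {
  force(input)
  cin <- gb$channels[input]
  nm <- sprintf("p%03d_conv%s", length(gb$nodes) + 1L, if (is.null(tag)) "" else tag)
  W <- array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
             c(k, k, cin, cout))
  g_param(gb, paste0(nm, ".W"), W)
  g_param(gb, paste0(nm, ".b"), numeric(cout))
  g_add(gb, list(op = "conv", inputs = input, pname = nm, k = as.integer(k)),
        channels = cout, level = gb$level[input])
}

g_convt2 <- function(gb, input, cout) {
  force(input)
  cin <- gb$channels[input]
  nm <- sprintf("p%03d_upconv", length(gb$nodes) + 1L)
  W <- array(stats::rnorm(4L * cin * cout, sd = sqrt(2 / cin)), c(2L, 2L, cin, cout))
  g_param(gb, paste0(nm, ".W"), W)
  g_param(gb, paste0(nm, ".b"), numeric(cout))
  g_add(gb, list(op = "convt2", inputs = input, pname = nm),
        channels = cout, level = gb$level[input] - 1L)
}

g_bn <- function(gb, input, momentum = 0.9, eps = 1e-3) {
  force(input)
  cc <- gb$channels[input]
  nm <- sprintf("p%03d_bn", length(gb$nodes) + 1L)
  g_param(gb, paste0(nm, ".gamma"), rep(1, cc))
  g_param(gb, paste0(nm, ".beta"), numeric(cc))
  gb$state[[paste0(nm, ".rmean")]] <- numeric(cc)
  gb$state[[paste0(nm, ".rvar")]] <- rep(1, cc)
  g_add(gb, list(op = "bn", inputs = input, pname = nm,
                 momentum = momentum, eps = eps),
        channels = cc, level = gb$level[input])
}

g_relu <- function(gb, input) {
  force(input)
  g_add(gb, list(op = "relu", inputs = input),
        channels = gb$channels[input], level = gb$level[input])
}

g_sigmoid <- function(gb, input) {
  force(input)
  g_add(gb, list(op = "sigmoid", inputs = input),
        channels = gb$channels[input], level = gb$level[input])
}

g_softmax <- function(gb, input) {
  force(input)
  g_add(gb, list(op = "softmax", inputs = input),
        channels = gb$channels[input], level = gb$level[input])
}

g_pool2 <- function(gb, input) {
  force(input)
  g_add(gb, list(op = "pool2", inputs = input),
        channels = gb$channels[input], level = gb$level[input] + 1L)
}

g_pool3s1 <- function(gb, input) {
  force(input)
  g_add(gb, list(op = "pool3s1", inputs = input),
        channels = gb$channels[input], level = gb$level[input])
}

g_gap <- function(gb, input) {
  force(input)
  g_add(gb, list(op = "gap", inputs = input),
        channels = gb$channels[input], level = NA_integer_)
}

g_addop <- function(gb, a, b) {
  force(a); force(b)
  stopifnot(gb$channels[a] == gb$channels[b])
  g_add(gb, list(op = "add", inputs = c(a, b)),
        channels = gb$channels[a], level = gb$level[a])
}

g_concat <- function(gb, inputs) {
  force(inputs)
  g_add(gb, list(op = "concat", inputs = inputs,
                 splits = gb$channels[inputs]),
        channels = sum(gb$channels[inputs]), level = gb$level[inputs[1L]])
}

g_scale_spatial <- function(gb, x, psi) {
  force(x); force(psi)
  g_add(gb, list(op = "scale_spatial", inputs = c(x, psi)),
        channels = gb$channels[x], level = gb$level[x])
}

g_scale_channel <- function(gb, x, s) {
  force(x); force(s)
  g_add(gb, list(op = "scale_channel", inputs = c(x, s)),
        channels = gb$channels[x], level = gb$level[x])
}

# -- execution --------------------------------------------------------------

net_forward <- function(net, x, training = FALSE, keep_cache = training) {
  nodes <- net$nodes
  params <- net$params
  state <- net$state
  outs <- vector("list", length(nodes))
  caches <- if (keep_cache) vector("list", length(nodes)) else NULL
  outs[[1L]] <- x
  for (id in seq_along(nodes)[-1L]) {
    nd <- nodes[[id]]
    ins <- nd$inputs
    a <- outs[[ins[1L]]]
    outs[[id]] <- switch(nd$op,
      conv = conv_fwd(a, params[[paste0(nd$pname, ".W")]],
                      params[[paste0(nd$pname, ".b")]]),
      convt2 = convt2_fwd(a, params[[paste0(nd$pname, ".W")]],
                          params[[paste0(nd$pname, ".b")]]),
      bn = {
        r <- bn_fwd(a, params[[paste0(nd$pname, ".gamma")]],
                    params[[paste0(nd$pname, ".beta")]],
                    state[[paste0(nd$pname, ".rmean")]],
                    state[[paste0(nd$pname, ".rvar")]],
                    training = training, momentum = nd$momentum, eps = nd$eps)
        if (training) {
          state[[paste0(nd$pname, ".rmean")]] <- r$rmean
          state[[paste0(nd$pname, ".rvar")]] <- r$rvar
        }
        if (keep_cache) caches[[id]] <- r$cache
        r$out
      },
      relu = relu_fwd(a),
      sigmoid = sigmoid_fwd(a),
      softmax = softmax_fwd(a),
      pool2 = {
        r <- maxpool2_fwd(a)
        if (keep_cache) caches[[id]] <- r$idx
        r$out
      },
      pool3s1 = {
        r <- maxpool3s1_fwd(a)
        if (keep_cache) caches[[id]] <- r$idx
        r$out
      },
      gap = gap_fwd(a),
      add = a + outs[[ins[2L]]],
      concat = {
        pieces <- outs[ins]
        d <- dim(pieces[[1L]])
        v <- unlist(pieces, use.names = FALSE)
        dim(v) <- c(d[1:3], sum(vapply(pieces, function(p) dim(p)[4L], 1L)))
        v
      },
      scale_spatial = scale_spatial_fwd(a, outs[[ins[2L]]]),
      scale_channel = scale_channel_fwd(a, outs[[ins[2L]]]),
      stop("unknown op: ", nd$op)
    )
  }
  list(out = outs[[length(nodes)]], outs = outs, caches = caches, state = state)
}

net_backward <- function(net, fwd, dout) {
  nodes <- net$nodes
  params <- net$params
  outs <- fwd$outs
  caches <- fwd$caches
  grads_out <- vector("list", length(nodes))
  pgrads <- list()
  grads_out[[length(nodes)]] <- dout
  acc <- function(cur, g) if (is.null(cur)) g else cur + g
  for (id in rev(seq_along(nodes)[-1L])) {
    g <- grads_out[[id]]
    if (is.null(g)) next
    nd <- nodes[[id]]
    ins <- nd$inputs
    a <- outs[[ins[1L]]]
    switch(nd$op,
      conv = {
        r <- conv_bwd(a, params[[paste0(nd$pname, ".W")]], g)
        pgrads[[paste0(nd$pname, ".W")]] <- r$dW
        pgrads[[paste0(nd$pname, ".b")]] <- r$db
        grads_out[[ins[1L]]] <- acc(grads_out[[ins[1L]]], r$dx)
      },
      convt2 = {
        r <- convt2_bwd(a, params[[paste0(nd$pname, ".W")]], g)
        pgrads[[paste0(nd$pname, ".W")]] <- r$dW
        pgrads[[paste0(nd$pname, ".b")]] <- r$db
        grads_out[[ins[1L]]] <- acc(grads_out[[ins[1L]]], r$dx)
      },
      bn = {
        r <- bn_bwd(g, params[[paste0(nd$pname, ".gamma")]], caches[[id]])
        pgrads[[paste0(nd$pname, ".gamma")]] <- r$dgamma
        pgrads[[paste0(nd$pname, ".beta")]] <- r$dbeta
        grads_out[[ins[1L]]] <- acc(grads_out[[ins[1L]]], r$dx)
      },
      relu = grads_out[[ins[1L]]] <- acc(grads_out[[ins[1L]]],
                                         relu_bwd(g, outs[[id]])),
      sigmoid = grads_out[[ins[1L]]] <- acc(grads_out[[ins[1L]]],
                                            sigmoid_bwd(g, outs[[id]])),
      softmax = grads_out[[ins[1L]]] <- acc(grads_out[[ins[1L]]],
                                            softmax_bwd(g, outs[[id]])),
      pool2 = grads_out[[ins[1L]]] <- acc(grads_out[[ins[1L]]],
                                          maxpool2_bwd(g, caches[[id]], dim(a))),
      pool3s1 = grads_out[[ins[1L]]] <- acc(grads_out[[ins[1L]]],
                                            maxpool3s1_bwd(g, caches[[id]], dim(a))),
      gap = grads_out[[ins[1L]]] <- acc(grads_out[[ins[1L]]], gap_bwd(g, dim(a))),
      add = {
        grads_out[[ins[1L]]] <- acc(grads_out[[ins[1L]]], g)
        grads_out[[ins[2L]]] <- acc(grads_out[[ins[2L]]], g)
      },
      concat = {
        off <- 0L
        for (k in seq_along(ins)) {
          ck <- nd$splits[k]
          gk <- g[, , , off + seq_len(ck), drop = FALSE]
          grads_out[[ins[k]]] <- acc(grads_out[[ins[k]]], gk)
          off <- off + ck
        }
      },
      scale_spatial = {
        r <- scale_spatial_bwd(g, a, outs[[ins[2L]]])
        grads_out[[ins[1L]]] <- acc(grads_out[[ins[1L]]], r$dx)
        grads_out[[ins[2L]]] <- acc(grads_out[[ins[2L]]], r$dscale)
      },
      scale_channel = {
        r <- scale_channel_bwd(g, a, outs[[ins[2L]]])
        grads_out[[ins[1L]]] <- acc(grads_out[[ins[1L]]], r$dx)
        grads_out[[ins[2L]]] <- acc(grads_out[[ins[2L]]], r$dscale)
      },
      stop("unknown op: ", nd$op)
    )
    grads_out[[id]] <- NULL   # free as we go
  }
  pgrads
}

# -- optimiser --------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
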