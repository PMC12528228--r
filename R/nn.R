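# Internal neural-network graph machinery.
#
# A network is a tree of nodes: "seq" (children applied in order), "concat"
# (parallel branches on a shared input, outputs concatenated along the
# channel axis) and leaf layers (zeropad, conv, bn, relu, maxpool, gap,
# dense, sigmoid).  Activations travel as arrays with dim (length,
# channels, batch); after global average pooling they become plain
# matrices (channels, batch).  Parameters live in a flat named list keyed
# by layer name, which keeps Adam updates and serialization trivial.

nn_seq <- function(...) list(type = "seq", children = list(...))
nn_concat <- function(branches) list(type = "concat", branches = branches)
nn_zeropad <- function(pad) list(type = "zeropad", pad = as.integer(pad))
nn_conv <- function(name, k, in_ch, out_ch, pad = 0L, stride = 1L) {
  list(type = "conv", name = name, k = as.integer(k),
       in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       pad = as.integer(pad), stride = as.integer(stride))
}
nn_bn <- function(name, c) list(type = "bn", name = name, c = as.integer(c))
nn_relu <- function() list(type = "relu")
nn_maxpool <- function(size, stride, pad = 0L) {
  list(type = "maxpool", size = as.integer(size), stride = as.integer(stride),
       pad = as.integer(pad))
}
nn_gap <- function() list(type = "gap")
nn_dense <- function(name, in_f, out_f) {
  list(type = "dense", name = name, in_f = as.integer(in_f),
       out_f = as.integer(out_f))
}
nn_sigmoid <- function() list(type = "sigmoid")

# Glorot-uniform initialisation, the framework default for sigmoid/ReLU
# stacks; seeded by the caller.
glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

nn_init_params <- function(node, params = list()) {
  switch(node$type,
    seq = {
      for (ch in node$children) params <- nn_init_params(ch, params)
      params
    },
    concat = {
      for (br in node$branches) params <- nn_init_params(br, params)
      params
    },
    conv = {
      fan_in <- node$in_ch * node$k
      fan_out <- node$out_ch * node$k
      params[[node$name]] <- list(
        W = glorot(node$out_ch, node$in_ch * node$k, fan_in, fan_out),
        b = numeric(node$out_ch))
      params
    },
    bn = {
      params[[node$name]] <- list(gamma = rep(1, node$c),
                                  beta = numeric(node$c))
      params
    },
    dense = {
      params[[node$name]] <- list(
        W = glorot(node$out_f, node$in_f, node$in_f, node$out_f),
        b = numeric(node$out_f))
      params
    },
    params)
}

# Batch-norm running statistics live in an environment so training updates
# them in place across the recursion.
nn_init_state <- function(node, state = new.env(parent = emptyenv())) {
  switch(node$type,
    seq = for (ch in node$children) nn_init_state(ch, state),
    concat = for (br in node$branches) nn_init_state(br, state),
    bn = assign(node$name, list(rmean = numeric(node$c),
                                rvar = rep(1, node$c)), envir = state))
  state
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

nn_fwd <- function(node, X, params, state, training = FALSE) {
  switch(node$type,
    seq = {
      caches <- vector("list", length(node$children))
      for (i in seq_along(node$children)) {
        r <- nn_fwd(node$children[[i]], X, params, state, training)
        X <- r$out
        caches[[i]] <- r$cache
      }
      list(out = X, cache = caches)
    },
    concat = {
      outs <- vector("list", length(node$branches))
      caches <- vector("list", length(node$branches))
      widths <- integer(length(node$branches))
      for (i in seq_along(node$branches)) {
        r <- nn_fwd(node$branches[[i]], X, params, state, training)
        outs[[i]] <- r$out
        caches[[i]] <- r$cache
        widths[i] <- dim(r$out)[2]
      }
      d <- dim(outs[[1]])
      out <- array(0, c(d[1], sum(widths), d[3]))
      at <- 0L
      for (i in seq_along(outs)) {
        out[, (at + 1L):(at + widths[i]), ] <- outs[[i]]
        at <- at + widths[i]
      }
      list(out = out, cache = list(caches = caches, widths = widths))
    },
    zeropad = {
      d <- dim(X)
      out <- array(0, c(d[1] + 2L * node$pad, d[2], d[3]))
      out[(node$pad + 1L):(node$pad + d[1]), , ] <- X
      list(out = out, cache = d[1])
    },
    conv = {
      p <- params[[node$name]]
      r <- cpp_conv1d_fwd(X, p$W, p$b, node$k, node$pad, node$stride)
      list(out = r$out, cache = X)
    },
    bn = {
      p <- params[[node$name]]
      st <- get(node$name, envir = state)
      r <- cpp_bn_fwd(X, p$gamma, p$beta, st$rmean, st$rvar,
                      BN_EPS, BN_MOMENTUM, training)
      if (training)
        assign(node$name, list(rmean = as.numeric(r$rmean),
                               rvar = as.numeric(r$rvar)), envir = state)
      list(out = r$out,
           cache = list(X = X, mean = as.numeric(r$mean),
                        var = as.numeric(r$var)))
    },
    relu = {
      mask <- X > 0
      X[!mask] <- 0
      list(out = X, cache = mask)
    },
    maxpool = {
      r <- cpp_maxpool1d_fwd(X, node$size, node$stride, node$pad)
      list(out = r$out, cache = list(argmax = r$argmax, l_in = dim(X)[1]))
    },
    gap = {
      d <- dim(X)
      out <- matrix(colMeans(matrix(X, nrow = d[1])), d[2], d[3])
      list(out = out, cache = d)
    },
    dense = {
      p <- params[[node$name]]
      list(out = p$W %*% X + p$b, cache = X)
    },
    sigmoid = {
      out <- 1 / (1 + exp(-X))
      list(out = out, cache = out)
    },
    stop("unknown node type: ", node$type))
}

# Backward pass: returns dX and accumulates parameter gradients into the
# `grads` environment keyed by layer name.
nn_bwd <- function(node, dY, cache, params, grads) {
  switch(node$type,
    seq = {
      for (i in rev(seq_along(node$children)))
        dY <- nn_bwd(node$children[[i]], dY, cache[[i]], params, grads)
      dY
    },
    concat = {
      widths <- cache$widths
      dX <- NULL
      at <- 0L
      for (i in seq_along(node$branches)) {
        dPart <- dY[, (at + 1L):(at + widths[i]), , drop = FALSE]
        at <- at + widths[i]
        dXi <- nn_bwd(node$branches[[i]], dPart, cache$caches[[i]],
                      params, grads)
        dX <- if (is.null(dX)) dXi else dX + dXi
      }
      dX
    },
    zeropad = {
      l <- cache
      dY[(node$pad + 1L):(node$pad + l), , , drop = FALSE]
    },
    conv = {
      p <- params[[node$name]]
      r <- cpp_conv1d_bwd(cache, p$W, dY, node$k, node$pad, node$stride)
      grads[[node$name]] <- list(W = r$dW, b = as.numeric(r$db))
      r$dX
    },
    bn = {
      p <- params[[node$name]]
      r <- cpp_bn_bwd(cache$X, dY, p$gamma, cache$mean, cache$var, BN_EPS)
      grads[[node$name]] <- list(gamma = as.numeric(r$dgamma),
                                 beta = as.numeric(r$dbeta))
      r$dX
    },
    relu = {
      dY[!cache] <- 0
      dY
    },
    maxpool = cpp_maxpool1d_bwd(cache$argmax, dY, cache$l_in),
    gap = {
      d <- cache
      array(rep(as.vector(dY), each = d[1]) / d[1], d)
    },
    dense = {
      p <- params[[node$name]]
      grads[[node$name]] <- list(W = dY %*% t(cache),
                                 b = rowSums(dY))
      t(p$W) %*% dY
    },
    sigmoid = dY * cache * (1 - cache),
    stop("unknown node type: ", node$type))
}

# Adam with the standard defaults (beta1 = 0.9, beta2 = 0.999, eps = 1e-8).
adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) lapply(p, function(x) x * 0))
  st$v <- lapply(params, function(p) lapply(p, function(x) x * 0))
  st
}

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (nm in ls(grads)) {
    g <- grads[[nm]]
    for (f in names(g)) {
      m <- beta1 * opt$m[[nm]][[f]] + (1 - beta1) * g[[f]]
      v <- beta2 * opt$v[[nm]][[f]] + (1 - beta2) * g[[f]]^2
      opt$m[[nm]][[f]] <- m
      opt$v[[nm]][[f]] <- v
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (m / corr1) / (sqrt(v / corr2) + eps)
    }
  }
  params
}

# Run code under a temporary RNG state so package randomness is seedable
# without clobbering the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
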