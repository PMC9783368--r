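# Layer objects for the network engine. Each layer is a plain list with a
# `type`, a named parameter list `par`, and (for batch norm) running buffers.
# `layer_forward()` returns the output plus whatever cache backward needs;
# `layer_backward()` returns the input gradient and per-parameter gradients.
# Stochastic layers (dropout) draw from the ambient RNG stream, so draw order
# is part of the engine's determinism contract.

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

layer_conv <- function(in_ch, out_ch, k = 3L, stride = 2L, pad = 1L) {
  list(
    type = "conv", k = as.integer(k), stride = as.integer(stride),
    pad = as.integer(pad), in_ch = in_ch, out_ch = out_ch,
    par = list(W = he_init(k * k * in_ch, out_ch, k * k * in_ch),
               b = rep(0, out_ch))
  )
}

layer_deconv <- function(in_ch, out_ch, stride = 2L, pad = 1L) {
  k <- 2L * pad + stride
  list(
    type = "deconv", stride = as.integer(stride), pad = as.integer(pad),
    k = k, in_ch = in_ch, out_ch = out_ch,
    par = list(W = he_init(k * k * out_ch, in_ch, k * k * in_ch),
               b = rep(0, out_ch))
  )
}

layer_dense <- function(in_dim, out_dim) {
  list(
    type = "dense", in_dim = in_dim, out_dim = out_dim,
    par = list(W = he_init(in_dim, out_dim, in_dim), b = rep(0, out_dim))
  )
}

layer_bn <- function(channels, momentum = 0.9, eps = 1e-5) {
  list(
    type = "bn", channels = channels, momentum = momentum, eps = eps,
    par = list(gamma = rep(1, channels), beta = rep(0, channels)),
    run_mean = rep(0, channels), run_var = rep(1, channels)
  )
}

layer_leaky <- function(slope = 0.01) list(type = "leaky", slope = slope, par = list())
layer_relu <- function() layer_leaky(0)
layer_tanh <- function() list(type = "tanh", par = list())
layer_dropout <- function(rate = 0.4) list(type = "dropout", rate = rate, par = list())
layer_flatten <- function() list(type = "flatten", par = list())
layer_gap <- function() list(type = "gap", par = list())
layer_reshape <- function(h, w, c) {
  list(type = "reshape", h = as.integer(h), w = as.integer(w),
       c = as.integer(c), par = list())
}

layer_forward <- function(layer, x, train = TRUE) {
  switch(layer$type,
    conv = {
      f <- conv_forward(x, layer$par$W, layer$par$b, layer$stride, layer$pad)
      list(y = f$y, cache = list(P = f$P, xdim = f$xdim))
    },
    deconv = {
      f <- deconv_forward(x, layer$par$W, layer$par$b, layer$stride, layer$pad)
      list(y = f$y, cache = list(x = x))
    },
    dense = {
      y <- x %*% layer$par$W
      y <- sweep(y, 2L, layer$par$b, "+")
      list(y = y, cache = list(x = x))
    },
    bn = bn_forward(layer, x, train),
    leaky = {
      pos <- x > 0
      y <- x * (layer$slope + (1 - layer$slope) * pos)
      list(y = y, cache = list(pos = pos))
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = list(y = y))
    },
    dropout = {
      if (train && layer$rate > 0) {
        mask <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
        dim(mask) <- dim(x)
        list(y = x * mask, cache = list(mask = mask))
      } else {
        list(y = x, cache = list(mask = NULL))
      }
    },
    flatten = {
      # (h,w,n,c) -> (n, h*w*c) with features ordered (h, w, channel)
      d <- dim(x)
      xm <- aperm(x, c(1L, 2L, 4L, 3L))
      list(y = t(matrix(xm, prod(d[c(1, 2, 4)]), d[3])),
           cache = list(d = d))
    },
    gap = {
      d <- dim(x)
      m <- matrix(x, d[1] * d[2], d[3] * d[4])
      list(y = matrix(colMeans(m), d[3], d[4]), cache = list(d = d))
    },
    reshape = {
      n <- nrow(x)
      y <- aperm(array(t(x), c(layer$h, layer$w, layer$c, n)),
                 c(1L, 2L, 4L, 3L))
      list(y = y, cache = list(n = n))
    },
    stop("unknown layer type: ", layer$type)
  )
}

bn_forward <- function(layer, x, train) {
  d <- dim(x)
  c <- d[4]
  m <- matrix(x, ncol = c)
  if (train) {
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu * mu
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  inv <- 1 / sqrt(v + layer$eps)
  N <- nrow(m)
  xhat <- (m - rep(mu, each = N)) * rep(inv, each = N)
  ym <- xhat * rep(layer$par$gamma, each = N) +
    rep(layer$par$beta, each = N)
  y <- ym
  dim(y) <- d
  upd <- NULL
  if (train) {
    upd <- list(
      run_mean = layer$momentum * layer$run_mean + (1 - layer$momentum) * mu,
      run_var = layer$momentum * layer$run_var + (1 - layer$momentum) * v
    )
  }
  list(y = y, cache = list(xhat = xhat, inv = inv, d = d, train = train),
       buffers = upd)
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- conv_backward(dy, cache$P, layer$par$W, cache$xdim,
                         layer$stride, layer$pad)
      list(dx = g$dx, grads = list(W = g$dW, b = g$db))
    },
    deconv = {
      g <- deconv_backward(dy, cache$x, layer$par$W, layer$stride, layer$pad)
      list(dx = g$dx, grads = list(W = g$dW, b = g$db))
    },
    dense = {
      list(dx = dy %*% t(layer$par$W),
           grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
    },
    bn = bn_backward(layer, cache, dy),
    leaky = {
      dx <- dy * (layer$slope + (1 - layer$slope) * cache$pos)
      list(dx = dx, grads = list())
    },
    tanh = list(dx = dy * (1 - cache$y^2), grads = list()),
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = list())
      else list(dx = dy * cache$mask, grads = list())
    },
    flatten = {
      d <- cache$d
      dx <- aperm(array(t(dy), c(d[1], d[2], d[4], d[3])),
                  c(1L, 2L, 4L, 3L))
      list(dx = dx, grads = list())
    },
    gap = {
      d <- cache$d
      per <- d[1] * d[2]
      dx <- array(rep(as.vector(dy) / per, each = per), d)
      list(dx = dx, grads = list())
    },
    reshape = {
      dxm <- aperm(dy, c(1L, 2L, 4L, 3L))
      list(dx = t(matrix(dxm, layer$h * layer$w * layer$c, cache$n)),
           grads = list())
    },
    stop("unknown layer type: ", layer$type)
  )
}

bn_backward <- function(layer, cache, dy) {
  d <- cache$d
  c <- d[4]
  dym <- matrix(dy, ncol = c)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  N <- nrow(dym)
  gi <- layer$par$gamma * cache$inv
  if (cache$train) {
    dxm <- (dym - rep(dbeta / N, each = N) -
              xhat * rep(dgamma / N, each = N)) * rep(gi, each = N)
  } else {
    dxm <- dym * rep(gi, each = N)
  }
  dx <- dxm
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}
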