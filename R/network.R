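# Sequential-network plumbing: forward/backward over a layer list, residual
# blocks for the feature extractor, and an Adam optimiser with configurable
# first-moment decay (the GAN uses beta1 = 0.5, the classifier 0.9).

new_network <- function(layers, input_shape, meta = list()) {
  structure(list(layers = layers, input_shape = input_shape, meta = meta),
            class = "plabgan_network")
}

#' @export
print.plabgan_network <- function(x, ...) {
  types <- vapply(x$layers, function(l) l$type, character(1))
  cat("<plabgan_network> ", paste(types, collapse = " -> "), "\n", sep = "")
  cat("  parameters: ", format(network_n_params(x), big.mark = ","), "\n",
      sep = "")
  invisible(x)
}

network_n_params <- function(net) {
  sum(vapply(net$layers,
             function(l) sum(vapply(l$par, length, 1L)), numeric(1)))
}

# Forward pass. Residual layers ("resblock") carry their own sub-layers.
# Returns final output, per-layer caches, per-layer outputs (for feature
# taps), and updated batch-norm buffers.
net_forward <- function(net, x, train = TRUE) {
  caches <- vector("list", length(net$layers))
  outs <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "resblock") {
      f <- resblock_forward(l, x, train)
      net$layers[[i]] <- f$layer
    } else {
      f <- layer_forward(l, x, train)
      if (!is.null(f$buffers)) {
        net$layers[[i]]$run_mean <- f$buffers$run_mean
        net$layers[[i]]$run_var <- f$buffers$run_var
      }
    }
    x <- f$y
    caches[[i]] <- f$cache
    outs[[i]] <- x
  }
  list(out = x, caches = caches, outs = outs, net = net)
}

# Backward from the output gradient down to `stop_at` (1 = full depth).
# Returns gradients shaped like each layer's `par`, plus the input gradient.
net_backward <- function(net, caches, dout, stop_at = 1L) {
  n <- length(net$layers)
  grads <- vector("list", n)
  dy <- dout
  for (i in rev(seq_len(n))) {
    if (i < stop_at) break
    l <- net$layers[[i]]
    if (l$type == "resblock") {
      b <- resblock_backward(l, caches[[i]], dy)
    } else {
      b <- layer_backward(l, caches[[i]], dy)
    }
    grads[[i]] <- b$grads
    dy <- b$dx
  }
  list(grads = grads, dx = dy)
}

# --- residual block (two 3x3 convs + BN + ReLU, optional 1x1 projection) ---

layer_resblock <- function(in_ch, out_ch, stride = 1L) {
  project <- stride != 1L || in_ch != out_ch
  sub <- list(
    conv1 = layer_conv(in_ch, out_ch, k = 3L, stride = stride, pad = 1L),
    bn1 = layer_bn(out_ch),
    relu1 = layer_relu(),
    conv2 = layer_conv(out_ch, out_ch, k = 3L, stride = 1L, pad = 1L),
    bn2 = layer_bn(out_ch)
  )
  if (project) {
    sub$proj <- layer_conv(in_ch, out_ch, k = 1L, stride = stride, pad = 0L)
  }
  list(type = "resblock", project = project, sub = sub,
       relu_out = layer_relu(), par = list())
}

resblock_forward <- function(layer, x, train) {
  cache <- list()
  h <- x
  for (nm in c("conv1", "bn1", "relu1", "conv2", "bn2")) {
    f <- layer_forward(layer$sub[[nm]], h, train)
    if (!is.null(f$buffers)) {
      layer$sub[[nm]]$run_mean <- f$buffers$run_mean
      layer$sub[[nm]]$run_var <- f$buffers$run_var
    }
    cache[[nm]] <- f$cache
    h <- f$y
  }
  if (layer$project) {
    fp <- layer_forward(layer$sub$proj, x, train)
    cache$proj <- fp$cache
    shortcut <- fp$y
  } else {
    shortcut <- x
  }
  s <- h + shortcut
  fr <- layer_forward(layer$relu_out, s, train)
  cache$relu_out <- fr$cache
  list(y = fr$y, cache = cache, layer = layer)
}

resblock_backward <- function(layer, cache, dy) {
  br <- layer_backward(layer$relu_out, cache$relu_out, dy)
  ds <- br$dx
  grads <- list()
  d <- ds
  for (nm in rev(c("conv1", "bn1", "relu1", "conv2", "bn2"))) {
    b <- layer_backward(layer$sub[[nm]], cache[[nm]], d)
    grads[[nm]] <- b$grads
    d <- b$dx
  }
  if (layer$project) {
    bp <- layer_backward(layer$sub$proj, cache$proj, ds)
    grads$proj <- bp$grads
    dx <- d + bp$dx
  } else {
    dx <- d + ds
  }
  list(dx = dx, grads = grads)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(net) {
  zero_like <- function(p) lapply(p, function(a) array(0, dim = dim(a) %||% length(a)))
  st <- lapply(net$layers, function(l) {
    if (l$type == "resblock") {
      lapply(l$sub, function(s) list(m = zero_like(s$par), v = zero_like(s$par)))
    } else {
      list(m = zero_like(l$par), v = zero_like(l$par))
    }
  })
  list(t = 0L, layers = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_apply_par <- function(par, grads, m, v, lr, b1, b2, t, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
    v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g * g
    mhat <- m[[nm]] / (1 - b1^t)
    vhat <- v[[nm]] / (1 - b2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, m = m, v = v)
}

# One Adam step over every layer that received a gradient.
adam_step <- function(net, grads, state, lr, b1 = 0.9, b2 = 0.999) {
  state$t <- state$t + 1L
  t <- state$t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g) || length(g) == 0) next
    l <- net$layers[[i]]
    if (l$type == "resblock") {
      for (nm in names(g)) {
        if (length(g[[nm]]) == 0) next
        u <- adam_apply_par(l$sub[[nm]]$par, g[[nm]],
                            state$layers[[i]][[nm]]$m,
                            state$layers[[i]][[nm]]$v, lr, b1, b2, t)
        net$layers[[i]]$sub[[nm]]$par <- u$par
        state$layers[[i]][[nm]]$m <- u$m
        state$layers[[i]][[nm]]$v <- u$v
      }
    } else {
      u <- adam_apply_par(l$par, g, state$layers[[i]]$m,
                          state$layers[[i]]$v, lr, b1, b2, t)
      net$layers[[i]]$par <- u$par
      state$layers[[i]]$m <- u$m
      state$layers[[i]]$v <- u$v
    }
  }
  list(net = net, state = state)
}

# Accumulate two gradient lists with the same structure (NULL-safe).
grads_add <- function(a, b, scale_b = 1) {
  if (is.null(a)) a <- vector("list", length(b))
  for (i in seq_along(b)) {
    if (is.null(b[[i]]) || length(b[[i]]) == 0) next
    if (is.null(a[[i]]) || length(a[[i]]) == 0) {
      a[[i]] <- rapply(b[[i]], function(x) x * scale_b, how = "replace")
    } else {
      a[[i]] <- add_nested(a[[i]], b[[i]], scale_b)
    }
  }
  a
}

add_nested <- function(a, b, s) {
  for (nm in names(b)) {
    if (is.list(b[[nm]])) a[[nm]] <- add_nested(a[[nm]], b[[nm]], s)
    else a[[nm]] <- a[[nm]] + s * b[[nm]]
  }
  a
}
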