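# Low-level tensor primitives for the network engine.
#
# Internal activation layout is (height, width, image, channel): with the
# channel dimension last, a convolution's im2col patch matrix, its output,
# batch-norm statistics and every gradient reshape directly in column-major
# order with no transposition. One precomputed index map per shape turns a
# convolution into a single BLAS matmul per batch. Transposed convolution
# reuses the same machinery by duality (its forward pass is the
# data-gradient of an ordinary convolution and vice versa).

.idx_cache <- new.env(parent = emptyenv())

# im2col index map for a padded batch (hp, wp, n, c): patch rows ordered
# (ki, kj, channel); columns ordered (oi, oj, image). Cached per shape.
im2col_idx <- function(hp, wp, n, c, k, s) {
  key <- paste(hp, wp, n, c, k, s, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  oh <- (hp - k) %/% s + 1L
  ow <- (wp - k) %/% s + 1L
  # map for image 1; images are offset by hp*wp in this layout
  ki <- rep(seq_len(k), times = k * c * oh * ow)
  kj <- rep(rep(seq_len(k), each = k), times = c * oh * ow)
  ch <- rep(rep(seq_len(c), each = k * k), times = oh * ow)
  oi <- rep(rep(seq_len(oh), each = k * k * c), times = ow)
  oj <- rep(seq_len(ow), each = k * k * c * oh)
  base <- (ki + (oi - 1L) * s) + (kj + (oj - 1L) * s - 1L) * hp +
    (ch - 1L) * hp * wp * n
  kkc <- k * k * c
  # columns ordered (positions of image 1, positions of image 2, ...)
  full <- as.integer(outer(base, (seq_len(n) - 1L) * hp * wp, `+`))
  out <- list(idx = full, oh = oh, ow = ow, kkc = kkc)
  .idx_cache[[key]] <- out
  out
}

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

unpad_hw <- function(xp, p, h, w) {
  if (p == 0L) return(xp)
  xp[p + seq_len(h), p + seq_len(w), , , drop = FALSE]
}

# Patch matrix for a padded batch: (k*k*c) x (oh*ow*n_img)... columns are
# ordered (position within image 1, position within image 2, ...).
im2col <- function(xp, k, s) {
  d <- dim(xp)
  map <- im2col_idx(d[1], d[2], d[3], d[4], k, s)
  matrix(xp[map$idx], nrow = map$kkc)
}

# Scatter-add the patch-gradient matrix back into a padded batch.
# dP: (oh*ow*n) x (k*k*c), rows ordered (oi, oj) within image blocks.
# Overlapping patches accumulate; the inner loop is compiled (scatter.cpp).
col2im <- function(dP, hp, wp, n, c, k, s) {
  map <- im2col_idx(hp, wp, n, c, k, s)
  dxp <- scatter_add_cols(map$idx, dP, hp * wp * n * c)
  dim(dxp) <- c(hp, wp, n, c)
  dxp
}

# Forward convolution. x: (h,w,n,c); W: (k*k*c) x m; b: length m.
conv_forward <- function(x, W, b, s, p) {
  d <- dim(x)
  k <- as.integer(round(sqrt(nrow(W) / d[4])))
  xp <- pad_hw(x, p)
  P <- im2col(xp, k, s)
  out <- crossprod(P, W)
  out <- out + rep(b, each = nrow(out))
  map <- im2col_idx(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4], k, s)
  y <- out
  dim(y) <- c(map$oh, map$ow, d[3], ncol(W))
  list(y = y, P = P, xdim = d)
}

# Full backward pass of a convolution given the cached patch matrix.
conv_backward <- function(dy, P, W, xdim, s, p) {
  d <- dim(dy)                      # (oh, ow, n, m)
  dY <- dy
  dim(dY) <- c(d[1] * d[2] * d[3], d[4])
  dW <- P %*% dY
  db <- colSums(dY)
  dP <- dY %*% t(W)
  c_in <- xdim[4]
  k <- as.integer(round(sqrt(nrow(W) / c_in)))
  dxp <- col2im(dP, xdim[1] + 2L * p, xdim[2] + 2L * p, xdim[3], c_in, k, s)
  dx <- unpad_hw(dxp, p, xdim[1], xdim[2])
  list(dx = dx, dW = dW, db = db)
}

# Data gradient only (doubles as the forward pass of a transposed conv).
conv_backward_data <- function(dy, W, xdim, s, p) {
  d <- dim(dy)
  dY <- dy
  dim(dY) <- c(d[1] * d[2] * d[3], d[4])
  dP <- dY %*% t(W)
  c_in <- xdim[4]
  k <- as.integer(round(sqrt(nrow(W) / c_in)))
  dxp <- col2im(dP, xdim[1] + 2L * p, xdim[2] + 2L * p, xdim[3], c_in, k, s)
  unpad_hw(dxp, p, xdim[1], xdim[2])
}

# Transposed convolution, stride s, pad p, kernel k = 2p + s: maps
# (h,w,n,m_in) to (s*h, s*w, n, m_out). W: (k*k*m_out) x m_in.
deconv_forward <- function(x, W, b, s, p) {
  d <- dim(x)
  m_out <- as.integer(nrow(W) / ((2L * p + s)^2))
  H <- s * d[1]; Wd <- s * d[2]
  y <- conv_backward_data(x, W, xdim = c(H, Wd, d[3], m_out), s = s, p = p)
  y <- y + rep(b, each = H * Wd * d[3])
  list(y = y, xdim = d, ydim = c(H, Wd, d[3], m_out))
}

deconv_backward <- function(dy, x, W, s, p) {
  d <- dim(x)
  k <- 2L * p + s
  dyp <- pad_hw(dy, p)
  P <- im2col(dyp, k = k, s = s)
  xM <- x
  dim(xM) <- c(d[1] * d[2] * d[3], d[4])
  dW <- P %*% xM
  db <- colSums(matrix(dy, ncol = dim(dy)[4]))
  dx <- crossprod(P, W)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}
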