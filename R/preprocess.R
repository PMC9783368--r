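# Image standardisation applied before pseudo-labelling and GAN training:
# bilinear resize to a square target, affine intensity mapping onto [-1, 1],
# and channel conversion. Augmentation expands a labelled set by seeded
# random rotation and integer translation.

# Clamp to [-1, 1] preserving dimensions (pmin/pmax drop them when the
# first argument is scalar).
clamp11 <- function(x) {
  d <- dim(x)
  x <- pmin(1, pmax(-1, x))
  dim(x) <- d
  x
}

# Bilinear interpolation weight matrix (pixel-centre convention): output
# pixel i samples source coordinate (i - 0.5) * n_in / n_out + 0.5 on the
# 1..n_in pixel grid, clamped at the borders.
bilinear_weights <- function(n_in, n_out) {
  s <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  s <- pmin(pmax(s, 1), n_in)
  i0 <- pmin(floor(s), n_in - 1L)
  if (n_in == 1L) i0 <- rep(1, n_out)
  fr <- s - i0
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    W[i, i0[i]] <- W[i, i0[i]] + (1 - fr[i])
    W[i, min(i0[i] + 1L, n_in)] <- W[i, min(i0[i] + 1L, n_in)] + fr[i]
  }
  W
}

#' Resize and intensity-normalise a batch of raw images
#'
#' Standardisation ahead of feature extraction and adversarial training:
#' bilinear resize to `target_size` x `target_size`, affine mapping of the
#' declared source intensity range onto [-1, 1], and channel conversion
#' (RGB to grey by channel mean, grey to RGB by replication). The source
#' range must be declared, never guessed from the data.
#'
#' @param images A numeric array: (n, h, w, c), (h, w, c) or (h, w).
#' @param target_size Output side length in pixels (default 128, the
#'   configuration used for clinical images).
#' @param channels Output channel count, 1 or 3 (default 1).
#' @param source_range Length-2 numeric, the nominal intensity range of the
#'   input (e.g. `c(0, 255)` for 8-bit, `c(0, 1)` for unit-scaled).
#' @return An (n, target_size, target_size, channels) array in [-1, 1].
#' @export
resize_normalize <- function(images, target_size = 128L, channels = 1L,
                             source_range = c(0, 255)) {
  if (length(source_range) != 2 || !all(is.finite(source_range)) ||
      source_range[2] <= source_range[1]) {
    stop("`source_range` must be two finite values (low, high)", call. = FALSE)
  }
  if (!channels %in% c(1L, 3L)) stop("`channels` must be 1 or 3", call. = FALSE)
  x <- as_batch(images)
  d <- dim(x)
  if (d[2] < 1 || d[3] < 1) stop("zero-area image", call. = FALSE)
  n <- d[1]; c_in <- d[4]
  Wr <- bilinear_weights(d[2], target_size)
  Wc <- t(bilinear_weights(d[3], target_size))
  out <- array(0, c(n, target_size, target_size, c_in))
  for (i in seq_len(n)) {
    for (ch in seq_len(c_in)) {
      out[i, , , ch] <- Wr %*% x[i, , , ch] %*% Wc
    }
  }
  out <- convert_channels(out, channels)
  lo <- source_range[1]; hi <- source_range[2]
  out <- 2 * (out - lo) / (hi - lo) - 1
  clamp11(out)
}

# Coerce (h,w), (h,w,c) or (n,h,w,c) numeric input to a rank-4 batch.
as_batch <- function(images) {
  if (inherits(images, "plabgan_dataset")) images <- images$images
  d <- dim(images)
  if (is.null(d)) stop("`images` must be an array", call. = FALSE)
  if (length(d) == 2) {
    array(images, c(1, d[1], d[2], 1))
  } else if (length(d) == 3) {
    array(images, c(1, d[1], d[2], d[3]))
  } else if (length(d) == 4) {
    images
  } else {
    stop("`images` must have 2-4 dimensions", call. = FALSE)
  }
}

convert_channels <- function(x, channels) {
  d <- dim(x)
  if (d[4] == channels) return(x)
  if (d[4] == 3 && channels == 1) {
    y <- array(0, c(d[1], d[2], d[3], 1))
    y[, , , 1] <- (x[, , , 1] + x[, , , 2] + x[, , , 3]) / 3
    y
  } else if (d[4] == 1 && channels == 3) {
    array(rep(x, 3), c(d[1], d[2], d[3], 3))
  } else {
    stop(sprintf("cannot convert %d channels to %d", d[4], channels),
         call. = FALSE)
  }
}

# Rotate one (h,w,c) image about its centre by `deg` degrees (bilinear,
# border value -1: normalised black), then shift by integer (dy, dx).
rotate_translate <- function(img, deg, dy, dx) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  th <- deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  # inverse map: output pixel samples the source rotated the other way
  sy <- cy + cos(th) * (yy - cy) - sin(th) * (xx - cx) - dy
  sx <- cx + sin(th) * (yy - cy) + cos(th) * (xx - cx) - dx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  out <- array(-1, d)
  gather <- function(yi, xi, ch) {
    ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
    v <- matrix(-1, h, w)
    idx <- cbind(yi[ok], xi[ok])
    v[ok] <- img[, , ch][idx]
    v
  }
  for (ch in seq_len(d[3])) {
    v00 <- gather(y0, x0, ch)
    v01 <- gather(y0, x0 + 1, ch)
    v10 <- gather(y0 + 1, x0, ch)
    v11 <- gather(y0 + 1, x0 + 1, ch)
    out[, , ch] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
      fy * ((1 - fx) * v10 + fx * v11)
  }
  clamp11(out)
}

#' Augment a labelled set by rotation and translation
#'
#' Expands the dataset `factor`-fold: copy 0 is the identity, copies
#' `1..factor-1` apply a seeded random rotation in
#' `[-max_rotation_deg, +max_rotation_deg]` and an integer translation in
#' `[-max_translation_px, +max_translation_px]` per axis. Uncovered borders
#' are filled with -1 (the normalised black level). Labels propagate
#' unchanged, so the label multiset ratio is preserved exactly.
#'
#' @param data A labelled dataset.
#' @param factor Integer expansion factor (>= 1); 1 returns the input.
#' @param max_rotation_deg Maximum absolute rotation in degrees (default 15,
#'   small enough to keep class-defining structure inside the frame).
#' @param max_translation_px Maximum absolute translation per axis in pixels
#'   (default: image size / 16).
#' @param seed Integer seed.
#' @return A labelled dataset with `factor * n` images.
#' @export
augment <- function(data, factor, max_rotation_deg = 15,
                    max_translation_px = NULL, seed = 1L) {
  stopifnot(inherits(data, "plabgan_dataset"), !is.null(data$labels))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    stop("`factor` must be an integer >= 1", call. = FALSE)
  }
  d <- dim(data$images)
  if (is.null(max_translation_px)) max_translation_px <- d[2] %/% 16L
  if (factor == 1L) return(data)
  n <- d[1]
  out <- array(0, c(n * factor, d[2], d[3], d[4]))
  out[seq_len(n), , , ] <- data$images
  with_seed(seed, {
    for (cp in seq_len(factor - 1L)) {
      for (i in seq_len(n)) {
        deg <- stats::runif(1, -max_rotation_deg, max_rotation_deg)
        dy <- sample(-max_translation_px:max_translation_px, 1)
        dx <- sample(-max_translation_px:max_translation_px, 1)
        img <- array(data$images[i, , , ], d[2:4])
        out[cp * n + i, , , ] <- rotate_translate(img, deg, dy, dx)
      }
    }
  })
  new_dataset(out, labels = rep(data$labels, factor),
              n_classes = data$n_classes)
}
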