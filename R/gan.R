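# The adversarial pair. The generator maps standard-normal noise through a
# dense layer reshaped to a (size/4, size/4, base_channels) tensor and two
# stride-2 transposed-convolution blocks up to the image size, with a Tanh
# output (so values are strictly inside (-1, 1)). At the clinical
# configuration (128 x 128 x 1, base 256) the dense reshape is 32 x 32 x 256.
# The discriminator is three stride-2 3x3 convolution blocks (LeakyReLU
# slope 0.01; batch norm on blocks 2-3) at widths 32/64/128, then flatten,
# dropout and a dense layer to K+1 logits.

#' Build the generator network
#'
#' @param image_size Output image side length (must be divisible by 4).
#' @param channels Output channels (1 or 3).
#' @param latent_dim Length of the standard-normal noise vector.
#' @param base_channels Channel count of the dense reshape (default 256, the
#'   clinical configuration; smaller values give a lighter model for small
#'   synthetic images).
#' @param seed Integer seed for weight initialisation.
#' @return A `plabgan_generator` object.
#' @export
plabgan_generator <- function(image_size = 128L, channels = 1L,
                              latent_dim = 100L, base_channels = 256L,
                              seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size %% 4L != 0L) {
    stop("`image_size` must be divisible by 4", call. = FALSE)
  }
  s4 <- image_size %/% 4L
  mid <- max(base_channels %/% 2L, channels)
  net <- with_seed(seed, new_network(list(
    layer_dense(latent_dim, s4 * s4 * base_channels),
    layer_reshape(s4, s4, base_channels),
    layer_deconv(base_channels, mid, stride = 2L, pad = 1L),
    layer_bn(mid),
    layer_leaky(0.01),
    layer_deconv(mid, channels, stride = 2L, pad = 1L),
    layer_tanh()
  ), input_shape = c(latent_dim)))
  structure(list(net = net, image_size = image_size, channels = channels,
                 latent_dim = latent_dim, base_channels = base_channels,
                 seed = seed),
            class = "plabgan_generator")
}

#' @export
print.plabgan_generator <- function(x, ...) {
  cat(sprintf(
    "<plabgan_generator> z[%d] -> %dx%dx%d -> %dx%dx%d (%s params)\n",
    x$latent_dim, x$image_size %/% 4L, x$image_size %/% 4L, x$base_channels,
    x$image_size, x$image_size, x$channels,
    format(network_n_params(x$net), big.mark = ",")))
  invisible(x)
}

#' Build the (K+1)-class discriminator network
#'
#' @param image_size Input image side length (divisible by 8).
#' @param channels Input channels.
#' @param n_classes Number of real classes K; the head emits K+1 logits.
#' @param widths Channel widths of the three convolution blocks
#'   (default `c(32, 64, 128)`).
#' @param dropout Dropout rate after flatten (default 0.4).
#' @param seed Integer seed for weight initialisation.
#' @return A `plabgan_discriminator` object.
#' @export
plabgan_discriminator <- function(image_size = 128L, channels = 1L,
                                  n_classes = 7L, widths = c(32L, 64L, 128L),
                                  dropout = 0.4, seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size %% 8L != 0L) {
    stop("`image_size` must be divisible by 8", call. = FALSE)
  }
  s8 <- image_size %/% 8L
  flat_dim <- s8 * s8 * widths[3]
  net <- with_seed(seed, new_network(list(
    layer_conv(channels, widths[1], k = 3L, stride = 2L, pad = 1L),
    layer_leaky(0.01),
    layer_conv(widths[1], widths[2], k = 3L, stride = 2L, pad = 1L),
    layer_bn(widths[2]),
    layer_leaky(0.01),
    layer_conv(widths[2], widths[3], k = 3L, stride = 2L, pad = 1L),
    layer_bn(widths[3]),
    layer_leaky(0.01),
    layer_flatten(),
    layer_dropout(dropout),
    layer_dense(flat_dim, n_classes + 1L)
  ), input_shape = c(image_size, image_size, channels),
     meta = list(flatten_index = 9L, n_classes = n_classes)))
  structure(list(net = net, image_size = image_size, channels = channels,
                 n_classes = n_classes, widths = widths, dropout = dropout,
                 seed = seed),
            class = "plabgan_discriminator")
}

#' @export
print.plabgan_discriminator <- function(x, ...) {
  cat(sprintf(
    "<plabgan_discriminator> %dx%dx%d -> %d+1 logits (%s params)\n",
    x$image_size, x$image_size, x$channels, x$n_classes,
    format(network_n_params(x$net), big.mark = ",")))
  invisible(x)
}

#' Sample generator noise and produce images
#'
#' @param generator A `plabgan_generator`.
#' @param n Number of images.
#' @param seed Optional seed for the noise draw; when `NULL` the ambient RNG
#'   stream is used (as inside the training loop).
#' @return An (n, size, size, channels) array with values in (-1, 1).
#' @export
generate_images <- function(generator, n, seed = NULL) {
  z <- if (is.null(seed)) {
    matrix(stats::rnorm(n * generator$latent_dim), n)
  } else {
    with_seed(seed, matrix(stats::rnorm(n * generator$latent_dim), n))
  }
  fwd <- net_forward(generator$net, z, train = FALSE)
  aperm(fwd$out, c(3L, 1L, 2L, 4L))
}

# Forward the discriminator, returning logits (n x K+1), flatten-layer
# features, caches and updated batch-norm buffers.
disc_forward <- function(disc, x_hwcn, train = TRUE) {
  fwd <- net_forward(disc$net, x_hwcn, train = train)
  list(logits = fwd$out,
       features = fwd$outs[[disc$net$meta$flatten_index]],
       caches = fwd$caches, net = fwd$net)
}

#' Classify images with the trained discriminator
#'
#' The predicted label is the argmax over the first K class probabilities —
#' the synthetic class is excluded — with ties broken toward the lowest
#' index. Inference mode: dropout off, batch-norm running statistics.
#'
#' @param discriminator A `plabgan_discriminator`.
#' @param images Image batch (array or dataset) matching the input shape.
#' @return Integer labels in `0..K-1`.
#' @export
classify <- function(discriminator, images) {
  stopifnot(inherits(discriminator, "plabgan_discriminator"))
  x <- as_batch(images)
  d <- dim(x)
  expect <- c(discriminator$image_size, discriminator$image_size,
              discriminator$channels)
  if (!all(d[2:4] == expect)) {
    stop(sprintf("image shape %s does not match discriminator input %s",
                 paste(d[2:4], collapse = "x"),
                 paste(expect, collapse = "x")), call. = FALSE)
  }
  K <- discriminator$n_classes
  labels <- integer(d[1])
  for (ix in split(seq_len(d[1]), ceiling(seq_len(d[1]) / 64))) {
    f <- disc_forward(discriminator, aperm(x[ix, , , , drop = FALSE],
                                           c(2L, 3L, 1L, 4L)), train = FALSE)
    p <- class_probabilities(f$logits)
    labels[ix] <- max.col(p[, seq_len(K), drop = FALSE],
                          ties.method = "first") - 1L
  }
  labels
}

#' Generator loss
#'
#' Default `feature_matching` mode: squared Euclidean distance between the
#' batch-mean flatten-layer activations of the discriminator on real versus
#' generated images — a statistic-matching objective that stabilises
#' adversarial training. `adversarial` mode: `-mean(ln(1 - p_fake))` on the
#' generated batch (the natural-log non-saturating form of the classic
#' generator objective).
#'
#' @param real_images Real image batch (array, (n, h, w, c)).
#' @param noise Latent matrix (n x latent_dim).
#' @param generator,discriminator The adversarial pair.
#' @param mode `"feature_matching"` (default) or `"adversarial"`.
#' @return Scalar loss.
#' @export
generator_loss <- function(real_images, noise, generator, discriminator,
                           mode = c("feature_matching", "adversarial")) {
  mode <- match.arg(mode)
  x <- as_batch(real_images)
  if (dim(x)[1] < 1 || nrow(noise) < 1) {
    stop("empty batch", call. = FALSE)
  }
  gf <- net_forward(generator$net, noise, train = FALSE)
  if (mode == "feature_matching") {
    fr <- disc_forward(discriminator, aperm(x, c(2L, 3L, 1L, 4L)),
                       train = FALSE)
    fg <- disc_forward(discriminator, gf$out, train = FALSE)
    sum((colMeans(fr$features) - colMeans(fg$features))^2)
  } else {
    fg <- disc_forward(discriminator, gf$out, train = FALSE)
    p <- class_probabilities(fg$logits)
    mean(-log(pmax(1 - p[, ncol(p)], LOG_CLAMP)))
  }
}
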