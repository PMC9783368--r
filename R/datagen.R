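#' Specification for a synthetic image dataset
#'
#' Defines a seeded, fully reproducible synthetic dataset with `n_classes`
#' visually distinct classes. Each class is a Gabor-like grating — a
#' class-specific orientation and spatial frequency under a class-specific
#' Gaussian envelope — so class separation in pixel and CNN feature space
#' degrades smoothly as `noise_sd` grows. The generator stands in for
#' clinical image corpora (chest X-rays, histopathology) in every test:
#' it reproduces their *structure* (K classes, small labelled pool, large
#' unlabelled pool, [-1, 1] intensities), not their appearance.
#'
#' @param n_classes Number of classes K (>= 2).
#' @param n_per_class Images generated per class (>= 1).
#' @param image_size Side length in pixels of the square images (>= 8).
#' @param channels 1 (greyscale) or 3 (RGB).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise on the
#'   [-1, 1] intensity scale; 0 gives noise-free class templates.
#' @param seed Integer seed; the same spec (including seed) always yields a
#'   bit-identical dataset.
#' @return An object of class `synth_spec`.
#' @examples
#' spec <- synth_spec(n_classes = 4, n_per_class = 10, image_size = 32)
#' data <- make_synthetic_dataset(spec)
#' data
#' @export
synth_spec <- function(n_classes = 4L, n_per_class = 100L, image_size = 32L,
                       channels = 1L, noise_sd = 0.1, seed = 1L) {
  n_classes <- as.integer(n_classes)
  n_per_class <- as.integer(n_per_class)
  image_size <- as.integer(image_size)
  channels <- as.integer(channels)
  if (is.na(n_classes) || n_classes < 2L) {
    stop("`n_classes` must be an integer >= 2", call. = FALSE)
  }
  if (is.na(n_per_class) || n_per_class < 1L) {
    stop("`n_per_class` must be an integer >= 1", call. = FALSE)
  }
  if (is.na(image_size) || image_size < 8L) {
    stop("`image_size` must be an integer >= 8", call. = FALSE)
  }
  if (!channels %in% c(1L, 3L)) {
    stop("`channels` must be 1 or 3", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be a nonnegative real", call. = FALSE)
  }
  structure(list(n_classes = n_classes, n_per_class = n_per_class,
                 image_size = image_size, channels = channels,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_spec> %d classes x %d images, %dx%dx%d, noise sd %.3g, seed %d\n",
    x$n_classes, x$n_per_class, x$image_size, x$image_size, x$channels,
    x$noise_sd, x$seed))
  invisible(x)
}

# Noise-free class template: oriented grating under a Gaussian envelope whose
# centre, orientation and frequency are deterministic functions of the class
# index. Values lie in [-1, 1] by construction (|cos| <= 1, envelope <= 1).
class_template <- function(k, image_size, channels) {
  s <- image_size
  g <- seq(-1, 1, length.out = s)
  xg <- matrix(g, s, s, byrow = TRUE)   # column coordinate
  yg <- matrix(g, s, s)                 # row coordinate
  theta <- pi * k / 7.3 + 0.37         # irrational-ish spacing: no repeats
  freq <- 2 + (k %% 4)
  cx <- 0.45 * cos(2.399963 * k)       # golden-angle blob placement
  cy <- 0.45 * sin(2.399963 * k)
  env <- exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * 0.35^2))
  out <- array(0, c(s, s, channels))
  for (ch in seq_len(channels)) {
    phase <- (ch - 1) * pi / 3
    grating <- cos(2 * pi * freq * (xg * cos(theta) + yg * sin(theta)) + phase)
    out[, , ch] <- grating * env
  }
  out
}

new_dataset <- function(images, labels = NULL, n_classes = NULL,
                        hidden_labels = NULL) {
  obj <- list(images = images, labels = labels, n_classes = n_classes)
  if (!is.null(hidden_labels)) {
    sealed <- new.env(parent = emptyenv())
    sealed$labels <- hidden_labels
    attr(obj, "sealed_truth") <- sealed
  }
  class(obj) <- "plabgan_dataset"
  obj
}

#' @export
print.plabgan_dataset <- function(x, ...) {
  d <- dim(x$images)
  kind <- if (is.null(x$labels)) "unlabelled" else "labelled"
  cat(sprintf("<plabgan_dataset> %d %s images, %dx%dx%d",
              d[1], kind, d[2], d[3], d[4]))
  if (!is.null(x$labels)) {
    cat(sprintf(", %d classes", length(unique(x$labels))))
  }
  cat("\n")
  invisible(x)
}

n_images <- function(data) dim(data$images)[1]

#' Generate a synthetic labelled image dataset
#'
#' Draws `n_classes * n_per_class` images: the class template plus additive
#' Gaussian pixel noise of sd `noise_sd`, clipped to [-1, 1]. Deterministic
#' in the spec (including its seed).
#'
#' @param spec A [synth_spec()].
#' @return A labelled dataset: `images` is an (n, size, size, channels)
#'   array with values in [-1, 1]; `labels` are integers in `0..K-1`.
#' @export
make_synthetic_dataset <- function(spec) {
  if (!inherits(spec, "synth_spec")) {
    stop("`spec` must be created by synth_spec()", call. = FALSE)
  }
  s <- spec$image_size
  n <- spec$n_classes * spec$n_per_class
  images <- array(0, c(n, s, s, spec$channels))
  labels <- rep(0:(spec$n_classes - 1L), each = spec$n_per_class)
  templates <- lapply(0:(spec$n_classes - 1L), class_template,
                      image_size = s, channels = spec$channels)
  with_seed(spec$seed, {
    for (i in seq_len(n)) {
      img <- templates[[labels[i] + 1L]]
      if (spec$noise_sd > 0) {
        img <- img + stats::rnorm(length(img), sd = spec$noise_sd)
      }
      images[i, , , ] <- clamp11(img)
    }
  })
  new_dataset(images, labels = labels, n_classes = spec$n_classes)
}

#' Stratified split into a labelled set and an unlabelled pool
#'
#' Emulates the semi-supervised study design: a small labelled budget per
#' class and a large unlabelled remainder. The unlabelled pool's true labels
#' are retained only in a sealed field for evaluation (see
#' [unlabelled_truth()]); its public interface exposes no labels.
#'
#' @param data A labelled dataset.
#' @param n_labelled_per_class Labelled budget per class; must not exceed any
#'   class count.
#' @param seed Integer seed driving the stratified draw.
#' @return A list with elements `labelled` and `unlabelled`; the partition is
#'   disjoint and exhaustive.
#' @export
split_labelled_unlabelled <- function(data, n_labelled_per_class, seed = 1L) {
  stopifnot(inherits(data, "plabgan_dataset"))
  if (is.null(data$labels)) {
    stop("`data` must be labelled", call. = FALSE)
  }
  counts <- table(data$labels)
  if (any(counts < n_labelled_per_class)) {
    stop("`n_labelled_per_class` exceeds the size of at least one class",
         call. = FALSE)
  }
  lab_idx <- with_seed(seed, {
    unlist(lapply(sort(unique(data$labels)), function(k) {
      ix <- which(data$labels == k)
      sample(ix, n_labelled_per_class)
    }))
  })
  lab_idx <- sort(lab_idx)
  unlab_idx <- setdiff(seq_len(n_images(data)), lab_idx)
  labelled <- new_dataset(data$images[lab_idx, , , , drop = FALSE],
                          labels = data$labels[lab_idx],
                          n_classes = data$n_classes)
  unlabelled <- new_dataset(data$images[unlab_idx, , , , drop = FALSE],
                            n_classes = data$n_classes,
                            hidden_labels = data$labels[unlab_idx])
  list(labelled = labelled, unlabelled = unlabelled)
}

#' Retrieve the sealed true labels of an unlabelled pool
#'
#' Evaluation-only accessor: semi-supervised code never touches this. The
#' truth is stored in a sealed environment, not as a list field, so pipeline
#' code cannot consume it accidentally.
#'
#' @param data An unlabelled dataset produced by [split_labelled_unlabelled()].
#' @return Integer vector of true labels, or an error if none are sealed.
#' @export
unlabelled_truth <- function(data) {
  sealed <- attr(data, "sealed_truth")
  if (is.null(sealed)) {
    stop("no sealed truth stored for this dataset", call. = FALSE)
  }
  sealed$labels
}
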