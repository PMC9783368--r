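# File interchange: datasets as directories of PNG files with a
# `manifest.csv` (columns filename, label; label empty for unlabelled
# images), packed `.rds` array bundles, pseudo-label CSVs, and network
# checkpoints with a config hash.

#' Write a dataset to a directory of PNG files with a manifest
#'
#' Intensities are mapped from [-1, 1] to [0, 1] for PNG encoding. The
#' manifest has columns `filename` and `label`; for an unlabelled pool the
#' label column is empty (sealed truth is never written).
#'
#' @param data A dataset (labelled or unlabelled).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "plabgan_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_images(data)
  fnames <- sprintf("img_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    img <- array(data$images[i, , , ], dim(data$images)[2:4])
    img01 <- (clamp11(img) + 1) / 2
    if (dim(img01)[3] == 1L) dim(img01) <- dim(img01)[1:2]
    png::writePNG(img01, file.path(dir, fnames[i]))
  }
  labels <- if (is.null(data$labels)) rep("", n) else data$labels
  utils::write.csv(data.frame(filename = fnames, label = labels),
                   file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Read a dataset from a manifest directory
#'
#' Reads `manifest.csv` plus the PNG/TIFF images it lists. PNG intensities
#' (source range [0, 1]) are mapped to [-1, 1]. An empty/missing label
#' column yields an unlabelled dataset.
#'
#' @param dir Directory containing `manifest.csv`.
#' @param channels Target channel count (default: as stored).
#' @return A `plabgan_dataset`.
#' @export
read_dataset <- function(dir, channels = NULL) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir, call. = FALSE)
  man <- utils::read.csv(mf, colClasses = "character")
  n <- nrow(man)
  imgs <- vector("list", n)
  for (i in seq_len(n)) {
    imgs[[i]] <- read_image(file.path(dir, man$filename[i]))
  }
  d <- dim(imgs[[1]])
  images <- array(0, c(n, d))
  for (i in seq_len(n)) images[i, , , ] <- imgs[[i]]
  images <- 2 * images - 1
  if (!is.null(channels)) {
    images <- convert_channels(images, channels)
  }
  labels <- NULL
  if ("label" %in% names(man) && any(nzchar(man$label))) {
    if (!all(nzchar(man$label))) {
      stop("manifest mixes labelled and unlabelled rows", call. = FALSE)
    }
    labels <- as.integer(man$label)
  }
  new_dataset(images, labels = labels,
              n_classes = if (!is.null(labels)) max(labels) + 1L else NULL)
}

# Single raster file -> (h, w, c) array in [0, 1].
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("png")) {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the tiff package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  d <- dim(img)
  if (length(d) == 2) {
    array(img, c(d, 1L))
  } else if (d[3] == 4L) {
    img[, , 1:3, drop = FALSE]  # drop alpha
  } else {
    img
  }
}

#' Write / read a packed array bundle
#'
#' A single-file alternative to the PNG directory: an `.rds` list with
#' elements `images` (n, h, w, c array in [-1, 1]) and `labels`
#' (integer or NULL).
#'
#' @param data A dataset.
#' @param path Bundle file path.
#' @return `path` (writer) or a `plabgan_dataset` (reader).
#' @export
write_bundle <- function(data, path) {
  stopifnot(inherits(data, "plabgan_dataset"))
  saveRDS(list(images = data$images, labels = data$labels), path)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  b <- readRDS(path)
  new_dataset(b$images, labels = b$labels,
              n_classes = if (!is.null(b$labels)) max(b$labels) + 1L else NULL)
}

#' Write pseudo labels to CSV
#'
#' Columns: index (1-based within the pool), pseudo_label, margin.
#'
#' @param pseudo A `pseudo_labels` or `pseudo_labelled_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pseudo_csv <- function(pseudo, path) {
  utils::write.csv(data.frame(index = seq_along(pseudo$pseudo_labels),
                              pseudo_label = pseudo$pseudo_labels,
                              margin = pseudo$margin),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Stable hash of a configuration list (for checkpoint integrity).
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2L)
  unname(tools::md5sum(tmp))
}

#' Save / load a network checkpoint
#'
#' Serialises a fitted object (extractor, generator, discriminator or full
#' fit) together with a hash of its configuration; loading verifies the
#' hash.
#'
#' @param object The object to checkpoint.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored object (load).
#' @export
save_checkpoint <- function(object, path) {
  cfg <- object$config %||% list()
  saveRDS(list(object = object, hash = config_hash(cfg)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- ck$object$config %||% list()
  if (!identical(ck$hash, config_hash(cfg))) {
    stop("checkpoint config hash mismatch", call. = FALSE)
  }
  ck$object
}
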