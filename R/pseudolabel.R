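# Pseudo-labelling: a compact residual CNN is trained on the labelled pool
# with a K-way softmax head; global-average-pooled penultimate features are
# extracted for the unlabelled pool; per-class feature centroids are fitted;
# each unlabelled image receives the label of its nearest centroid under a
# weighted squared Euclidean distance, optionally after K-means refinement.

# Residual stack in the CIFAR-style family: depth = 6n + 2 (three stages of
# n blocks at widths base, 2*base, 4*base; stride-2 at stage transitions).
# depth 20 reproduces the classic 20-layer configuration; depth 8 (n = 1)
# is the compact variant used on small synthetic images.
build_extractor_net <- function(input_shape, n_classes, depth = 8L,
                                base_filters = 16L) {
  if ((depth - 2L) %% 6L != 0L) {
    stop("`depth` must be 6n + 2 (8, 14, 20, ...)", call. = FALSE)
  }
  nb <- (depth - 2L) %/% 6L
  ch <- input_shape[3]
  layers <- list(layer_conv(ch, base_filters, k = 3L, stride = 1L, pad = 1L),
                 layer_bn(base_filters), layer_relu())
  widths <- base_filters * c(1L, 2L, 4L)
  in_ch <- base_filters
  for (stage in 1:3) {
    for (b in seq_len(nb)) {
      stride <- if (stage > 1 && b == 1) 2L else 1L
      layers <- c(layers, list(layer_resblock(in_ch, widths[stage], stride)))
      in_ch <- widths[stage]
    }
  }
  layers <- c(layers, list(layer_gap(), layer_dense(in_ch, n_classes)))
  new_network(layers, input_shape,
              meta = list(feature_dim = in_ch, n_classes = n_classes,
                          gap_index = length(layers) - 1L, depth = depth))
}

#' Train the feature extractor on the labelled pool
#'
#' Fits a compact residual CNN with a K-way softmax head by categorical
#' cross-entropy (Adam). The trained body — up to and including global
#' average pooling — is the feature map used for centroid fitting and
#' pseudo-label assignment; the classification head is only used here.
#'
#' @param labelled A labelled dataset with at least 2 classes and 2 images
#'   per class.
#' @param epochs Training epochs; 0 returns the seeded initialisation.
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 16).
#' @param depth Residual depth, 6n + 2 (default 8; 20 gives the classic
#'   20-layer stack).
#' @param base_filters Width of the first stage (default 16).
#' @param seed Integer seed driving initialisation and batch order.
#' @return A `plabgan_extractor`: the trained network, its feature dimension
#'   and a per-epoch training trace (loss, accuracy).
#' @export
train_feature_extractor <- function(labelled, epochs = 20L, lr = 1e-3,
                                    batch_size = 16L, depth = 8L,
                                    base_filters = 16L, seed = 1L) {
  stopifnot(inherits(labelled, "plabgan_dataset"))
  if (is.null(labelled$labels)) stop("`labelled` has no labels", call. = FALSE)
  counts <- table(labelled$labels)
  if (length(counts) < 2L) {
    stop("labelled set must contain at least 2 classes", call. = FALSE)
  }
  if (any(counts < 2L)) {
    stop("every class needs at least 2 labelled images", call. = FALSE)
  }
  K <- labelled$n_classes %||% length(counts)
  d <- dim(labelled$images)
  input_shape <- d[2:4]
  net <- with_seed(derive_seed(seed, 1L),
                   build_extractor_net(input_shape, K, depth, base_filters))
  trace <- list()
  if (epochs > 0) {
    x_all <- aperm(labelled$images, c(2L, 3L, 1L, 4L))
    y_all <- labelled$labels
    n <- d[1]
    opt <- adam_init(net)
    old <- rng_scope_open(derive_seed(seed, 2L))
    on.exit(rng_scope_close(old), add = TRUE)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x_all[, , idx, , drop = FALSE]
        yb <- y_all[idx]
        fwd <- net_forward(net, xb, train = TRUE)
        net <- fwd$net
        probs <- class_probabilities(fwd$out)
        ep_loss <- ep_loss + ce_loss(probs, yb) * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(probs, ties.method = "first") - 1L == yb)
        dlogits <- ce_grad(probs, yb)
        bk <- net_backward(net, fwd$caches, dlogits)
        up <- adam_step(net, bk$grads, opt, lr, b1 = 0.9)
        net <- up$net
        opt <- up$state
      }
      trace[[ep]] <- c(loss = ep_loss / n, accuracy = ep_correct / n)
    }
  }
  trace_tbl <- if (length(trace)) {
    tibble::tibble(epoch = seq_along(trace),
                   loss = vapply(trace, `[[`, 0, "loss"),
                   accuracy = vapply(trace, `[[`, 0, "accuracy"))
  } else {
    tibble::tibble(epoch = integer(), loss = numeric(), accuracy = numeric())
  }
  structure(list(net = net, n_classes = K, input_shape = input_shape,
                 feature_dim = net$meta$feature_dim, trace = trace_tbl,
                 config = list(epochs = epochs, lr = lr,
                               batch_size = batch_size, depth = depth,
                               base_filters = base_filters, seed = seed)),
            class = "plabgan_extractor")
}

#' @export
print.plabgan_extractor <- function(x, ...) {
  cat(sprintf("<plabgan_extractor> depth %d, %d classes, feature dim %d\n",
              x$config$depth, x$n_classes, x$feature_dim))
  if (nrow(x$trace)) {
    cat(sprintf("  final training accuracy: %.3f\n",
                x$trace$accuracy[nrow(x$trace)]))
  }
  invisible(x)
}

# Mean categorical cross-entropy and its logit gradient (labels 0-based).
ce_loss <- function(probs, labels) {
  p <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

ce_grad <- function(probs, labels) {
  g <- probs
  g[cbind(seq_len(nrow(probs)), labels + 1L)] <-
    g[cbind(seq_len(nrow(probs)), labels + 1L)] - 1
  g / nrow(probs)
}

#' Extract deep features from images
#'
#' Deterministic inference-mode forward pass (batch-norm running statistics,
#' no dropout) up to the global-average-pooling layer.
#'
#' @param extractor A trained [train_feature_extractor()] object.
#' @param images An image batch (array or dataset) matching the extractor's
#'   input shape.
#' @return A numeric matrix, one feature row per image.
#' @export
extract_features <- function(extractor, images) {
  stopifnot(inherits(extractor, "plabgan_extractor"))
  x <- as_batch(images)
  d <- dim(x)
  if (!all(d[2:4] == extractor$input_shape)) {
    stop(sprintf("image shape %s does not match extractor input %s",
                 paste(d[2:4], collapse = "x"),
                 paste(extractor$input_shape, collapse = "x")), call. = FALSE)
  }
  # chunked inference: keeps the im2col working set cache-resident
  chunks <- split(seq_len(d[1]), ceiling(seq_len(d[1]) / 64))
  out <- matrix(0, d[1], extractor$feature_dim)
  for (ix in chunks) {
    xi <- aperm(x[ix, , , , drop = FALSE], c(2L, 3L, 1L, 4L))
    fwd <- net_forward(extractor$net, xi, train = FALSE)
    out[ix, ] <- fwd$outs[[extractor$net$meta$gap_index]]
  }
  out
}

#' Fit per-class feature centroids
#'
#' Centroid i is the arithmetic mean of the feature rows with label i;
#' per-dimension distance weights start at all-ones (plain squared
#' Euclidean distance).
#'
#' @param features Numeric feature matrix (rows = images).
#' @param labels Integer labels in `0..K-1`; every class must be present.
#' @return A `centroid_model` with `centroids` (K x d), `weights` (length d)
#'   and per-class training counts.
#' @export
fit_centroids <- function(features, labels) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  K <- max(labels) + 1L
  if (!all(0:(K - 1L) %in% labels)) {
    stop("every class 0..K-1 must be present in `labels`", call. = FALSE)
  }
  cent <- matrix(0, K, ncol(features))
  counts <- integer(K)
  for (k in 0:(K - 1L)) {
    rows <- features[labels == k, , drop = FALSE]
    cent[k + 1L, ] <- colMeans(rows)
    counts[k + 1L] <- nrow(rows)
  }
  structure(list(centroids = cent, weights = rep(1, ncol(features)),
                 counts = counts, K = K),
            class = "centroid_model")
}

#' @export
print.centroid_model <- function(x, ...) {
  cat(sprintf("<centroid_model> %d classes, feature dim %d\n",
              x$K, ncol(x$centroids)))
  invisible(x)
}

# Weighted squared Euclidean distances, n x K. Computed per class by direct
# differencing (numerically symmetric, so exact ties stay exact).
centroid_distances <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != ncol(model$centroids)) {
    stop("feature dimension does not match the centroid model", call. = FALSE)
  }
  w <- model$weights
  D <- matrix(0, nrow(features), model$K)
  ft <- t(features)
  for (k in seq_len(model$K)) {
    D[, k] <- colSums(w * (ft - model$centroids[k, ])^2)
  }
  D
}

#' Refine centroids with anchored K-means (Lloyd iterations)
#'
#' Each iteration assigns every unlabelled feature to its nearest centroid
#' (weighted squared Euclidean) and recomputes centroid i as the mean of its
#' assigned points pooled with the original labelled class mean, weighted by
#' the labelled class count — the labelled evidence anchors each cluster.
#' `max_iter = 0` (the default elsewhere) returns the model unchanged: pure
#' nearest-centroid assignment. The pooled objective (assigned distances
#' plus the anchored labelled mass) is non-increasing across iterations.
#'
#' @param model A [fit_centroids()] model.
#' @param unlabelled_features Feature matrix of the unlabelled pool.
#' @param max_iter Maximum Lloyd iterations (>= 0).
#' @param tol Stop when the largest centroid shift falls below `tol`.
#' @return The refined `centroid_model`, carrying an `sse` attribute with
#'   the per-iteration objective trace.
#' @export
refine_kmeans <- function(model, unlabelled_features, max_iter = 10L,
                          tol = 1e-6) {
  stopifnot(inherits(model, "centroid_model"), max_iter >= 0)
  if (max_iter == 0L) return(model)
  X <- as.matrix(unlabelled_features)
  anchors <- model$centroids
  counts <- model$counts
  w <- model$weights
  sse <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- centroid_distances(model, X)
    assign <- max.col(-D, ties.method = "first")
    obj <- sum(D[cbind(seq_len(nrow(X)), assign)]) +
      sum(counts * rowSums(sweep((anchors - model$centroids)^2, 2L, w, "*")))
    sse <- c(sse, obj)
    new_cent <- model$centroids
    for (k in seq_len(model$K)) {
      pts <- X[assign == k, , drop = FALSE]
      new_cent[k, ] <- (counts[k] * anchors[k, ] + colSums(pts)) /
        (counts[k] + nrow(pts))
    }
    shift <- max(abs(new_cent - model$centroids))
    model$centroids <- new_cent
    if (shift < tol) break
  }
  attr(model, "sse") <- sse
  model
}

#' Assign pseudo labels by nearest weighted centroid
#'
#' For each feature row, the distance to class i is
#' `sum_d w_d * (f_d - centroid_{i,d})^2`; the pseudo label is the argmin,
#' with ties broken toward the lowest class index. Distances and the margin
#' (second-best minus best distance) are returned for confidence gating.
#'
#' @param model A `centroid_model`.
#' @param features Feature matrix with matching dimension.
#' @return A `pseudo_labels` object: `pseudo_labels` (0-based), `distances`
#'   (n x K) and `margin`.
#' @export
assign_pseudo_labels <- function(model, features) {
  stopifnot(inherits(model, "centroid_model"))
  D <- centroid_distances(model, features)
  lab <- apply(D, 1L, which.min) - 1L
  srt <- t(apply(D, 1L, sort))
  margin <- if (model$K >= 2) srt[, 2] - srt[, 1] else rep(Inf, nrow(D))
  structure(list(pseudo_labels = as.integer(lab), distances = D,
                 margin = margin, K = model$K),
            class = "pseudo_labels")
}

#' @export
print.pseudo_labels <- function(x, ...) {
  cat(sprintf("<pseudo_labels> %d images over %d classes; median margin %.3g\n",
              length(x$pseudo_labels), x$K, stats::median(x$margin)))
  invisible(x)
}

#' Pseudo-label an unlabelled pool end to end
#'
#' Convenience wrapper: extract features of the unlabelled pool, assign
#' nearest-centroid pseudo labels (optionally K-means-refined), and attach
#' the images so the result can feed adversarial training directly. Images
#' whose margin falls below `margin_threshold` are dropped (confidence
#' gating; the default 0 keeps all).
#'
#' @param unlabelled Unlabelled dataset.
#' @param extractor Trained feature extractor.
#' @param centroids Fitted `centroid_model`.
#' @param refine_iter Lloyd refinement iterations (default 0: pure
#'   nearest-centroid, the primary reading of the procedure).
#' @param margin_threshold Minimum margin to retain an image (default 0).
#' @return A `pseudo_labelled_set`: images, pseudo labels, distances, margin.
#' @export
pseudo_label_dataset <- function(unlabelled, extractor, centroids,
                                 refine_iter = 0L, margin_threshold = 0) {
  feats <- extract_features(extractor, unlabelled)
  model <- refine_kmeans(centroids, feats, max_iter = refine_iter)
  pl <- assign_pseudo_labels(model, feats)
  keep <- pl$margin >= margin_threshold
  structure(list(images = unlabelled$images[keep, , , , drop = FALSE],
                 pseudo_labels = pl$pseudo_labels[keep],
                 distances = pl$distances[keep, , drop = FALSE],
                 margin = pl$margin[keep], K = pl$K,
                 model = model),
            class = "pseudo_labelled_set")
}

#' @export
print.pseudo_labelled_set <- function(x, ...) {
  cat(sprintf("<pseudo_labelled_set> %d images, %d classes\n",
              length(x$pseudo_labels), x$K))
  invisible(x)
}
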