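# Evaluation: multi-class accuracy, confusion matrices and per-class
# recall-style accuracies (within-class correct fraction), plus a
# one-vs-rest binary accuracy per class since the binary
# (TP+TN)/(TP+TN+FP+FN) formula is ambiguous for K > 2.

#' Classification accuracy
#'
#' Fraction of predictions equal to the truth. For the binary case this is
#' exactly (TP+TN)/(TP+TN+FP+FN).
#'
#' @param predictions Integer predicted labels.
#' @param truth Integer true labels of the same length.
#' @return A real in [0, 1].
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop("`predictions` and `truth` must have equal length", call. = FALSE)
  }
  if (length(truth) == 0) stop("empty label vectors", call. = FALSE)
  mean(predictions == truth)
}

#' Evaluate a discriminator on a labelled test set
#'
#' Classifies the test images, tallies the K x K confusion matrix, and
#' reports overall accuracy, per-class accuracy (within-class correct
#' fraction, i.e. recall) and per-class one-vs-rest binary accuracy.
#'
#' @param discriminator A trained `plabgan_discriminator`.
#' @param test A non-empty labelled dataset.
#' @return An `eval_report`.
#' @export
evaluate <- function(discriminator, test) {
  stopifnot(inherits(test, "plabgan_dataset"))
  if (is.null(test$labels) || n_images(test) == 0) {
    stop("`test` must be a non-empty labelled dataset", call. = FALSE)
  }
  preds <- classify(discriminator, test)
  eval_report(preds, test$labels, discriminator$n_classes)
}

#' Build an evaluation report from labels
#'
#' @param predictions Integer predicted labels in `0..K-1`.
#' @param truth Integer true labels in `0..K-1`.
#' @param n_classes Number of classes K (default: inferred).
#' @return An `eval_report`: overall accuracy, per-class accuracies,
#'   confusion matrix (rows = truth, columns = prediction), sample count.
#' @export
eval_report <- function(predictions, truth, n_classes = NULL) {
  K <- n_classes %||% (max(c(predictions, truth)) + 1L)
  lv <- 0:(K - 1L)
  cm <- table(factor(truth, levels = lv), factor(predictions, levels = lv))
  cm <- matrix(as.integer(cm), K, K,
               dimnames = list(truth = lv, prediction = lv))
  row_n <- rowSums(cm)
  per_class <- ifelse(row_n > 0, diag(cm) / row_n, NA_real_)
  n <- length(truth)
  ovr <- vapply(seq_len(K), function(k) {
    tp <- cm[k, k]
    fn <- row_n[k] - tp
    fp <- sum(cm[, k]) - tp
    tn <- n - tp - fn - fp
    (tp + tn) / n
  }, numeric(1))
  structure(list(
    overall_accuracy = sum(diag(cm)) / n,
    per_class_accuracy = as.numeric(per_class),
    ovr_accuracy = as.numeric(ovr),
    confusion_matrix = cm,
    n_samples = n, n_classes = K), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, overall accuracy = %.4f\n",
              x$n_samples, x$overall_accuracy))
  cat("  per-class accuracy:",
      paste(sprintf("%.3f", x$per_class_accuracy), collapse = " "), "\n")
  invisible(x)
}

#' Tidy an evaluation report into one row per class
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with class, within-class accuracy, one-vs-rest
#'   accuracy and truth count.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    class = 0:(x$n_classes - 1L),
    accuracy = x$per_class_accuracy,
    ovr_accuracy = x$ovr_accuracy,
    n = rowSums(x$confusion_matrix))
}

#' One-row summary of an evaluation report
#'
#' @inheritParams tidy.eval_report
#' @return A one-row tibble: overall accuracy, class count, sample count.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(accuracy = x$overall_accuracy,
                 n_classes = x$n_classes, n = x$n_samples)
}

#' Tidy a fitted model's training trace
#'
#' @param x A `plabgan_fit`.
#' @param ... Unused.
#' @return The per-iteration trace tibble.
#' @export
tidy.plabgan_fit <- function(x, ...) x$trace

#' One-row summary of a fitted model
#'
#' @inheritParams tidy.plabgan_fit
#' @return A one-row tibble: iterations run, final losses, last validation
#'   accuracy.
#' @export
glance.plabgan_fit <- function(x, ...) {
  tr <- x$trace
  va <- tr$val_accuracy[!is.na(tr$val_accuracy)]
  tibble::tibble(
    iterations = nrow(tr),
    l_d = if (nrow(tr)) tr$l_d[nrow(tr)] else NA_real_,
    g_loss = if (nrow(tr)) tr$g_loss[nrow(tr)] else NA_real_,
    val_accuracy = if (length(va)) va[length(va)] else NA_real_,
    alpha = x$config$alpha, beta = x$config$beta)
}

#' Plot the training trace of a fitted model
#'
#' Loss components and (when traced) validation accuracy against iteration.
#'
#' @param object A `plabgan_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plabgan_fit <- function(object, ...) {
  tr <- object$trace
  long <- tibble::tibble(
    iteration = rep(tr$iteration, 3),
    loss = c(tr$l_d, tr$l_label, tr$g_loss),
    component = rep(c("discriminator", "labelled term", "generator"),
                    each = nrow(tr)))
  long <- long[is.finite(long$loss), , drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report as a confusion heatmap
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  cm <- object$confusion_matrix
  df <- tibble::tibble(
    truth = factor(rep(rownames(cm), ncol(cm))),
    prediction = factor(rep(colnames(cm), each = nrow(cm))),
    count = as.vector(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(levels(df$truth))) +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
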