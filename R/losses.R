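# The (K+1)-class discriminator loss system. The discriminator emits K+1
# logits: classes 1..K are the real classes, class K+1 is the synthetic
# class. Three terms combine into the discriminator objective
#   l_d = l_label + alpha * l_unlabel + beta * l_gen
# with natural logarithms throughout and a 1e-12 clamp inside every log.

LOG_CLAMP <- 1e-12

#' Softmax probabilities over K+1 classes
#'
#' Numerically stable softmax (max-subtraction) over the last dimension.
#' Rows sum to 1 within 1e-6 for any finite logits.
#'
#' @param logits A numeric vector of length K+1 or an n x (K+1) matrix.
#' @return Probabilities with the same shape as the input.
#' @export
class_probabilities <- function(logits) {
  vec <- is.null(dim(logits))
  m <- if (vec) matrix(logits, nrow = 1) else as.matrix(logits)
  if (!all(is.finite(m))) stop("logits must be finite", call. = FALSE)
  z <- m - apply(m, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  if (vec) as.vector(p) else p
}

as_prob_matrix <- function(probs) {
  m <- if (is.null(dim(probs))) matrix(probs, nrow = 1) else as.matrix(probs)
  if (!all(is.finite(m)) || any(m < -1e-9) ||
      any(abs(rowSums(m) - 1) > 1e-6)) {
    stop("`probs` must be rows of valid probabilities summing to 1",
         call. = FALSE)
  }
  m
}

#' Labelled-sample classification loss
#'
#' Mean categorical cross-entropy of the true class under the (K+1)-way
#' head: `-mean(ln p(y | x))`. Ground-truth labels are always real classes,
#' so every label must be `< K`.
#'
#' @param probs n x (K+1) matrix (or single vector) of class probabilities.
#' @param labels Integer labels in `0..K-1`.
#' @return Scalar loss (natural log, clamped at 1e-12).
#' @export
loss_labelled <- function(probs, labels) {
  p <- as_prob_matrix(probs)
  K <- ncol(p) - 1L
  if (any(labels < 0 | labels >= K)) {
    stop("labels must lie in 0..K-1 (the synthetic class is never a label)",
         call. = FALSE)
  }
  stopifnot(length(labels) == nrow(p))
  mean(-log(pmax(p[cbind(seq_len(nrow(p)), labels + 1L)], LOG_CLAMP)))
}

#' Unlabelled-sample realness loss
#'
#' `-mean(ln(1 - p_fake))`: unlabelled images are real, so the probability
#' mass on the synthetic class K+1 is penalised.
#'
#' @inheritParams loss_labelled
#' @return Scalar loss.
#' @export
loss_unlabelled <- function(probs) {
  p <- as_prob_matrix(probs)
  mean(-log(pmax(1 - p[, ncol(p)], LOG_CLAMP)))
}

#' Generated-sample detection loss
#'
#' `-mean(ln p_fake)`: generated images should be routed to the synthetic
#' class K+1.
#'
#' @inheritParams loss_labelled
#' @return Scalar loss.
#' @export
loss_generated <- function(probs) {
  p <- as_prob_matrix(probs)
  mean(-log(pmax(p[, ncol(p)], LOG_CLAMP)))
}

#' Composite discriminator loss
#'
#' `l_d = l_label + alpha * l_unlabel + beta * l_gen`. With
#' `alpha = beta = 0` the objective reduces to plain supervised
#' cross-entropy.
#'
#' @param l_label,l_unlabel,l_gen The three finite component losses.
#' @param alpha Weight on the unlabelled term (default 0.5).
#' @param beta Weight on the generated term (default 0.5).
#' @return Scalar composite loss.
#' @export
discriminator_loss <- function(l_label, l_unlabel, l_gen,
                               alpha = 0.5, beta = 0.5) {
  stopifnot(is.finite(l_label), is.finite(l_unlabel), is.finite(l_gen),
            alpha >= 0, beta >= 0)
  l_label + alpha * l_unlabel + beta * l_gen
}

# --- logit gradients of the three terms (used by the training loop) --------

# d(mean CE)/d logits for labelled samples: (p - onehot) / n.
grad_labelled <- function(probs, labels) {
  ce_grad(probs, labels)
}

# d(-mean ln(1 - p_fake))/d logits. For j <= K: p_j - p_j / (1 - p_fake);
# for the fake column: p_fake.
grad_unlabelled <- function(probs) {
  n <- nrow(probs)
  Kp1 <- ncol(probs)
  pf <- probs[, Kp1]
  g <- probs - probs / pmax(1 - pf, LOG_CLAMP)
  g[, Kp1] <- pf
  g / n
}

# d(-mean ln p_fake)/d logits: cross-entropy toward the fake class.
grad_generated <- function(probs) {
  n <- nrow(probs)
  g <- probs
  g[, ncol(probs)] <- g[, ncol(probs)] - 1
  g / n
}
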