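# Alternating adversarial training. Per iteration the discriminator sees an
# equal-sized labelled batch, optional pseudo-labelled and unlabelled
# batches, and a generated batch; it takes one Adam step on the composite
# loss l_d = l_label + alpha * l_unlabel + beta * l_gen. The generator is
# then updated with the discriminator frozen (feature matching by default).
# All randomness — batch indices, noise, dropout masks — flows from the
# config seed through one RNG stream whose draw order is fixed, so a run is
# bit-reproducible and the alpha = beta = 0 reduction is step-for-step
# identical to plain supervised training.

#' Training configuration for the adversarial classifier
#'
#' @param alpha Weight on the unlabelled realness loss (default 0.5, the
#'   setting found best in the grid sweep).
#' @param beta Weight on the generated-sample loss (default 0.5).
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size Sub-batch size for each of the labelled, pseudo,
#'   unlabelled and generated batches (default 16).
#' @param adam_beta1 Adam first-moment decay (default 0.5, the usual
#'   adversarial-training setting).
#' @param max_iterations Iteration budget.
#' @param seed Integer seed for initialisation and all sampling.
#' @param use_pseudo_labels Include the pseudo-labelled pool in the
#'   classification term (the full method); `FALSE` gives the plain
#'   semi-supervised ablation.
#' @param use_unlabelled Feed the unlabelled pool into the realness term.
#' @param use_generated Run the generator and adversarial terms; disabling
#'   this together with `use_unlabelled` and zero weights reduces training
#'   to a supervised classifier.
#' @param generator_loss_mode `"feature_matching"` (default) or
#'   `"adversarial"`.
#' @param latent_dim Noise vector length (default 100).
#' @param gen_base_channels Generator dense-reshape channels (default 256).
#' @param disc_widths Discriminator block widths (default `c(32, 64, 128)`).
#' @param dropout Discriminator dropout rate after flatten (default 0.4).
#' @param pseudo_weight Confidence weight on the pseudo-labelled
#'   classification term (default 1).
#' @param eval_every Validation cadence in iterations (default 50).
#' @param patience Early-stop patience in evaluations without improvement
#'   (default `Inf`: fixed iteration budget).
#' @return A `plabgan_config` list.
#' @export
plabgan_config <- function(alpha = 0.5, beta = 0.5, lr = 1e-4,
                           batch_size = 16L, adam_beta1 = 0.5,
                           max_iterations = 500L, seed = 1L,
                           use_pseudo_labels = TRUE, use_unlabelled = TRUE,
                           use_generated = TRUE,
                           generator_loss_mode = c("feature_matching",
                                                   "adversarial"),
                           latent_dim = 100L, gen_base_channels = 256L,
                           disc_widths = c(32L, 64L, 128L), dropout = 0.4,
                           pseudo_weight = 1, eval_every = 50L,
                           patience = Inf) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  if (lr <= 0) stop("lr must be positive", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (max_iterations < 0) stop("max_iterations must be >= 0", call. = FALSE)
  structure(list(
    alpha = alpha, beta = beta, lr = lr, batch_size = as.integer(batch_size),
    adam_beta1 = adam_beta1, max_iterations = as.integer(max_iterations),
    seed = as.integer(seed), use_pseudo_labels = use_pseudo_labels,
    use_unlabelled = use_unlabelled, use_generated = use_generated,
    generator_loss_mode = match.arg(generator_loss_mode),
    latent_dim = as.integer(latent_dim),
    gen_base_channels = as.integer(gen_base_channels),
    disc_widths = as.integer(disc_widths), dropout = dropout,
    pseudo_weight = pseudo_weight, eval_every = as.integer(eval_every),
    patience = patience), class = "plabgan_config")
}

# Partial discriminator forward up to the flatten layer (feature tap).
# Returns features, caches for the truncated stack, and the updated network
# (batch-norm buffers advance in train mode).
disc_forward_features <- function(disc, x_hwcn, train = TRUE) {
  fi <- disc$net$meta$flatten_index
  sub <- disc$net
  sub$layers <- sub$layers[seq_len(fi)]
  fwd <- net_forward(sub, x_hwcn, train = train)
  disc$net$layers[seq_len(fi)] <- fwd$net$layers
  list(features = fwd$out, caches = fwd$caches, disc = disc, sub = fwd$net)
}

#' Train the semi-supervised adversarial classifier
#'
#' Alternating optimisation: one Adam step on the discriminator's composite
#' loss, then one Adam step on the generator with the discriminator frozen.
#' Sub-batches (labelled / pseudo-labelled / unlabelled / generated) are
#' forwarded separately so each sees its own batch-norm statistics.
#'
#' @param labelled Labelled dataset (non-empty; labels in `0..K-1`).
#' @param unlabelled Optional unlabelled dataset for the realness term.
#' @param pseudo Optional [pseudo_label_dataset()] result: images that join
#'   the classification term under their pseudo labels (weight
#'   `cfg$pseudo_weight`).
#' @param cfg A [plabgan_config()].
#' @param val Optional labelled dataset for the validation-accuracy trace
#'   and early stopping.
#' @return A `plabgan_fit`: trained `discriminator` and `generator`, the
#'   per-iteration loss/accuracy `trace` (tibble), and the config.
#' @export
train_plabgan <- function(labelled, unlabelled = NULL, pseudo = NULL,
                          cfg = plabgan_config(), val = NULL) {
  stopifnot(inherits(labelled, "plabgan_dataset"), inherits(cfg, "plabgan_config"))
  if (is.null(labelled$labels) || n_images(labelled) == 0) {
    stop("`labelled` must be a non-empty labelled dataset", call. = FALSE)
  }
  d <- dim(labelled$images)
  size <- d[2]; channels <- d[4]
  K <- labelled$n_classes %||% (max(labelled$labels) + 1L)

  gen <- plabgan_generator(size, channels, cfg$latent_dim,
                           cfg$gen_base_channels,
                           seed = derive_seed(cfg$seed, 1L))
  disc <- plabgan_discriminator(size, channels, K, cfg$disc_widths,
                                cfg$dropout, seed = derive_seed(cfg$seed, 2L))

  x_lab <- aperm(labelled$images, c(2L, 3L, 1L, 4L))
  y_lab <- labelled$labels
  n_lab <- d[1]
  have_pseudo <- cfg$use_pseudo_labels && !is.null(pseudo) &&
    length(pseudo$pseudo_labels) > 0
  if (have_pseudo) {
    x_ps <- aperm(pseudo$images, c(2L, 3L, 1L, 4L))
    y_ps <- pseudo$pseudo_labels
    n_ps <- length(y_ps)
  }
  have_unlab <- cfg$use_unlabelled && !is.null(unlabelled) &&
    n_images(unlabelled) > 0
  if (have_unlab) {
    x_un <- aperm(unlabelled$images, c(2L, 3L, 1L, 4L))
    n_un <- dim(x_un)[4]
  }

  opt_d <- adam_init(disc$net)
  opt_g <- adam_init(gen$net)
  bs <- cfg$batch_size
  trace <- vector("list", cfg$max_iterations)
  best_val <- -Inf; since_best <- 0L
  stopped_at <- cfg$max_iterations

  old <- rng_scope_open(derive_seed(cfg$seed, 3L))
  on.exit(rng_scope_close(old), add = TRUE)

  iter <- 0L
  while (iter < cfg$max_iterations) {
    iter <- iter + 1L

    # --- discriminator step -------------------------------------------
    il <- sample.int(n_lab, bs, replace = TRUE)
    fl <- disc_forward(disc, x_lab[, , il, , drop = FALSE], train = TRUE)
    disc$net <- fl$net
    pl <- class_probabilities(fl$logits)
    l_label <- ce_loss(pl, y_lab[il])
    bk <- net_backward(disc$net, fl$caches, grad_labelled(pl, y_lab[il]))
    grads <- bk$grads

    if (have_pseudo) {
      ip <- sample.int(n_ps, bs, replace = TRUE)
      fp <- disc_forward(disc, x_ps[, , ip, , drop = FALSE], train = TRUE)
      disc$net <- fp$net
      pp <- class_probabilities(fp$logits)
      l_label <- l_label + cfg$pseudo_weight * ce_loss(pp, y_ps[ip])
      bkp <- net_backward(disc$net, fp$caches, grad_labelled(pp, y_ps[ip]))
      grads <- grads_add(grads, bkp$grads, cfg$pseudo_weight)
    }

    l_unlabel <- 0
    if (have_unlab) {
      iu <- sample.int(n_un, bs, replace = TRUE)
      fu <- disc_forward(disc, x_un[, , iu, , drop = FALSE], train = TRUE)
      disc$net <- fu$net
      pu <- class_probabilities(fu$logits)
      l_unlabel <- loss_unlabelled(pu)
      if (cfg$alpha > 0) {
        bku <- net_backward(disc$net, fu$caches, grad_unlabelled(pu))
        grads <- grads_add(grads, bku$grads, cfg$alpha)
      }
    }

    l_gen <- 0
    if (cfg$use_generated) {
      z <- matrix(stats::rnorm(bs * cfg$latent_dim), bs)
      gz <- net_forward(gen$net, z, train = TRUE)
      gen$net <- gz$net
      fg <- disc_forward(disc, gz$out, train = TRUE)
      disc$net <- fg$net
      pg <- class_probabilities(fg$logits)
      l_gen <- loss_generated(pg)
      if (cfg$beta > 0) {
        bkg <- net_backward(disc$net, fg$caches, grad_generated(pg))
        grads <- grads_add(grads, bkg$grads, cfg$beta)
      }
    }

    l_d <- discriminator_loss(l_label, l_unlabel, l_gen, cfg$alpha, cfg$beta)
    if (!is.finite(l_d)) {
      stop(sprintf("non-finite discriminator loss at iteration %d (l_label=%g, l_unlabel=%g, l_gen=%g)",
                   iter, l_label, l_unlabel, l_gen), call. = FALSE)
    }
    up <- adam_step(disc$net, grads, opt_d, cfg$lr, b1 = cfg$adam_beta1)
    disc$net <- up$net
    opt_d <- up$state

    # --- generator step (discriminator frozen) ------------------------
    g_loss <- NA_real_
    if (cfg$use_generated) {
      z2 <- matrix(stats::rnorm(bs * cfg$latent_dim), bs)
      gz2 <- net_forward(gen$net, z2, train = TRUE)
      gen$net <- gz2$net
      if (cfg$generator_loss_mode == "feature_matching") {
        x_real <- if (have_unlab) {
          x_un[, , iu, , drop = FALSE]
        } else {
          x_lab[, , il, , drop = FALSE]
        }
        fr <- disc_forward_features(disc, x_real, train = TRUE)
        disc <- fr$disc
        fgen <- disc_forward_features(disc, gz2$out, train = TRUE)
        disc <- fgen$disc
        diff <- colMeans(fr$features) - colMeans(fgen$features)
        g_loss <- sum(diff^2)
        dF <- matrix(rep(-2 * diff / bs, each = bs), bs)
        bkd <- net_backward(fgen$sub, fgen$caches, dF)
      } else {
        fgen_full <- disc_forward(disc, gz2$out, train = TRUE)
        disc$net <- fgen_full$net
        pg2 <- class_probabilities(fgen_full$logits)
        g_loss <- loss_unlabelled(pg2)
        bkd <- net_backward(disc$net, fgen_full$caches, grad_unlabelled(pg2))
      }
      bkgen <- net_backward(gen$net, gz2$caches, bkd$dx)
      upg <- adam_step(gen$net, bkgen$grads, opt_g, cfg$lr,
                       b1 = cfg$adam_beta1)
      gen$net <- upg$net
      opt_g <- upg$state
      if (!is.finite(g_loss)) {
        stop(sprintf("non-finite generator loss at iteration %d", iter),
             call. = FALSE)
      }
    }

    # --- logging / validation -----------------------------------------
    val_acc <- NA_real_
    if (!is.null(val) && (iter %% cfg$eval_every == 0L ||
                          iter == cfg$max_iterations)) {
      val_acc <- accuracy(classify(disc, val), val$labels)
      if (is.finite(cfg$patience)) {
        if (val_acc > best_val) {
          best_val <- val_acc
          since_best <- 0L
        } else {
          since_best <- since_best + 1L
        }
      }
    }
    trace[[iter]] <- c(iteration = iter, l_label = l_label,
                       l_unlabel = l_unlabel, l_gen = l_gen, l_d = l_d,
                       g_loss = g_loss, val_accuracy = val_acc)
    if (is.finite(cfg$patience) && since_best >= cfg$patience) {
      stopped_at <- iter
      break
    }
  }

  trace <- trace[seq_len(stopped_at)]
  trace_tbl <- if (length(trace)) {
    tibble::as_tibble(as.data.frame(do.call(rbind, trace)))
  } else {
    tibble::tibble(iteration = integer(), l_label = numeric(),
                   l_unlabel = numeric(), l_gen = numeric(),
                   l_d = numeric(), g_loss = numeric(),
                   val_accuracy = numeric())
  }
  structure(list(discriminator = disc, generator = gen, trace = trace_tbl,
                 config = cfg, n_classes = K),
            class = "plabgan_fit")
}

#' @export
print.plabgan_fit <- function(x, ...) {
  cat(sprintf("<plabgan_fit> %d classes, %d iterations\n",
              x$n_classes, nrow(x$trace)))
  if (nrow(x$trace)) {
    cat(sprintf("  final l_d = %.4f", x$trace$l_d[nrow(x$trace)]))
    va <- x$trace$val_accuracy[!is.na(x$trace$val_accuracy)]
    if (length(va)) cat(sprintf(", last val accuracy = %.3f", va[length(va)]))
    cat("\n")
  }
  invisible(x)
}

#' @export
predict.plabgan_fit <- function(object, newdata, ...) {
  classify(object$discriminator, newdata)
}
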