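# End-to-end experiment orchestration from a YAML/list configuration:
# simulate (or load) -> preprocess -> pseudo-label -> adversarial training
# -> evaluation, with a replicate protocol (n repeats under distinct seeds,
# mean +/- sample sd reported).

experiment_defaults <- function() {
  list(
    datagen = list(n_classes = 4L, n_per_class = 110L, image_size = 32L,
                   channels = 1L, noise_sd = 0.1,
                   n_labelled_per_class = 10L, n_test_per_class = 25L),
    preprocess = list(target_size = NULL, augment_factor = 1L,
                      max_rotation_deg = 15, max_translation_px = NULL),
    pseudolabel = list(epochs = 15L, depth = 8L, lr = 1e-3,
                       batch_size = 16L, base_filters = 16L,
                       refine_iter = 0L, margin_threshold = 0),
    plabgan = list(alpha = 0.5, beta = 0.5, lr = 1e-4, batch_size = 16L,
                   adam_beta1 = 0.5, max_iterations = 300L,
                   latent_dim = 64L, gen_base_channels = 64L,
                   dropout = 0.4, use_pseudo_labels = TRUE,
                   use_unlabelled = TRUE, use_generated = TRUE,
                   generator_loss_mode = "feature_matching",
                   pseudo_weight = 1, eval_every = 50L, patience = Inf),
    eval = list(repeats = 1L),
    seed = 1L,
    data_dir = NULL
  )
}

merge_config <- function(base, user, path = "") {
  bad <- setdiff(names(user), names(base))
  if (length(bad)) {
    stop("unknown config key(s): ",
         paste0(path, bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "$"))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load and validate an experiment configuration
#'
#' @param config A YAML file path or a nested list with (any of the) blocks
#'   `datagen`, `preprocess`, `pseudolabel`, `plabgan`, `eval`, plus `seed`.
#'   Unknown keys raise an error naming them.
#' @return The merged, validated configuration list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or YAML path",
                             call. = FALSE)
  merge_config(experiment_defaults(), config)
}

# One pipeline pass under one seed; returns the fit, reports and traces.
run_single <- function(cfg, seed) {
  dg <- cfg$datagen
  spec <- synth_spec(dg$n_classes, dg$n_per_class, dg$image_size,
                     dg$channels, dg$noise_sd, seed = derive_seed(seed, 11L))
  pool <- make_synthetic_dataset(spec)
  parts <- split_labelled_unlabelled(pool, dg$n_labelled_per_class,
                                     seed = derive_seed(seed, 12L))
  test <- make_synthetic_dataset(
    synth_spec(dg$n_classes, dg$n_test_per_class, dg$image_size,
               dg$channels, dg$noise_sd, seed = derive_seed(seed, 13L)))

  pp <- cfg$preprocess
  if (!is.null(pp$target_size) && pp$target_size != dg$image_size) {
    for (nm in c("labelled", "unlabelled")) {
      parts[[nm]]$images <- resize_normalize(
        parts[[nm]]$images, pp$target_size, dg$channels,
        source_range = c(-1, 1))
    }
    test$images <- resize_normalize(test$images, pp$target_size,
                                    dg$channels, source_range = c(-1, 1))
  }
  if (pp$augment_factor > 1L) {
    parts$labelled <- augment(parts$labelled, pp$augment_factor,
                              pp$max_rotation_deg, pp$max_translation_px,
                              seed = derive_seed(seed, 14L))
  }

  ps <- cfg$pseudolabel
  extractor <- train_feature_extractor(
    parts$labelled, epochs = ps$epochs, lr = ps$lr,
    batch_size = ps$batch_size, depth = ps$depth,
    base_filters = ps$base_filters, seed = derive_seed(seed, 15L))
  feats_lab <- extract_features(extractor, parts$labelled)
  centroids <- fit_centroids(feats_lab, parts$labelled$labels)
  pseudo <- NULL
  pseudo_acc <- NA_real_
  if (n_images(parts$unlabelled) > 0) {
    pseudo <- pseudo_label_dataset(parts$unlabelled, extractor, centroids,
                                   refine_iter = ps$refine_iter,
                                   margin_threshold = ps$margin_threshold)
    all_pl <- assign_pseudo_labels(pseudo$model,
                                   extract_features(extractor,
                                                    parts$unlabelled))
    pseudo_acc <- accuracy(all_pl$pseudo_labels,
                           unlabelled_truth(parts$unlabelled))
  }

  ga <- cfg$plabgan
  tcfg <- plabgan_config(
    alpha = ga$alpha, beta = ga$beta, lr = ga$lr,
    batch_size = ga$batch_size, adam_beta1 = ga$adam_beta1,
    max_iterations = ga$max_iterations, seed = derive_seed(seed, 16L),
    use_pseudo_labels = ga$use_pseudo_labels,
    use_unlabelled = ga$use_unlabelled, use_generated = ga$use_generated,
    generator_loss_mode = ga$generator_loss_mode,
    latent_dim = ga$latent_dim, gen_base_channels = ga$gen_base_channels,
    dropout = ga$dropout, pseudo_weight = ga$pseudo_weight,
    eval_every = ga$eval_every, patience = ga$patience)
  fit <- train_plabgan(parts$labelled, unlabelled = parts$unlabelled,
                       pseudo = pseudo, cfg = tcfg,
                       val = if (is.finite(ga$patience)) test else NULL)
  report <- evaluate(fit$discriminator, test)
  list(fit = fit, report = report, pseudo_accuracy = pseudo_acc,
       extractor = extractor)
}

#' Run a full replicated experiment from a configuration
#'
#' Executes the pipeline `repeats` times under distinct seeds
#' (`seed, seed + 1, ...`) and aggregates accuracy as mean +/- sample
#' standard deviation. With an output directory, persists the merged
#' config, a reproducibility manifest (seeds, package version), per-repeat
#' results and the final training trace.
#'
#' @param config YAML path or config list (see [load_config()]).
#' @param out Optional output directory for artifacts.
#' @return A `plabgan_experiment`: per-repeat tibble `results`, aggregate
#'   `mean_accuracy` / `sd_accuracy`, the per-repeat evaluation reports and
#'   the last repeat's fit.
#' @export
run_experiment <- function(config = list(), out = NULL) {
  cfg <- load_config(config)
  repeats <- cfg$eval$repeats
  rows <- vector("list", repeats)
  reports <- vector("list", repeats)
  fit <- NULL
  for (r in seq_len(repeats)) {
    seed_r <- as.integer(cfg$seed) + r - 1L
    one <- run_single(cfg, seed_r)
    rows[[r]] <- tibble::tibble(
      rep = r, seed = seed_r,
      pseudo_accuracy = one$pseudo_accuracy,
      accuracy = one$report$overall_accuracy)
    reports[[r]] <- one$report
    fit <- one$fit
  }
  results <- do.call(rbind, rows)
  obj <- structure(list(
    results = results,
    mean_accuracy = mean(results$accuracy),
    sd_accuracy = if (repeats > 1) stats::sd(results$accuracy) else NA_real_,
    reports = reports, fit = fit, config = cfg), class = "plabgan_experiment")
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(prune_nulls(cfg), file.path(out, "config.yaml"))
    jsonlite::write_json(
      list(seeds = results$seed,
           package_version = as.character(utils::packageVersion("plabgan")),
           r_version = R.version.string,
           config_hash = config_hash(cfg)),
      file.path(out, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    utils::write.csv(results, file.path(out, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$trace, file.path(out, "trace.csv"),
                     row.names = FALSE)
  }
  obj
}

prune_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, prune_nulls)
  x[!vapply(x, is.null, TRUE)]
}

#' @export
print.plabgan_experiment <- function(x, ...) {
  cat(sprintf("<plabgan_experiment> %d repeat(s): accuracy %.4f",
              nrow(x$results), x$mean_accuracy))
  if (!is.na(x$sd_accuracy)) cat(sprintf(" +/- %.4f", x$sd_accuracy))
  cat("\n")
  invisible(x)
}

#' @export
glance.plabgan_experiment <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy,
                 repeats = nrow(x$results),
                 mean_pseudo_accuracy = mean(x$results$pseudo_accuracy))
}

#' @export
tidy.plabgan_experiment <- function(x, ...) x$results

#' Sweep the loss weights alpha and beta over a grid
#'
#' Re-runs the experiment for every (alpha, beta) pair and collects mean
#' accuracy — the protocol behind choosing `alpha = beta = 0.5`.
#'
#' @param config Base configuration (YAML path or list).
#' @param alpha_grid,beta_grid Numeric vectors of weights to test.
#' @return A `plabgan_sweep`: tibble of `alpha`, `beta`, `accuracy`, `sd`.
#' @export
sweep_alpha_beta <- function(config = list(), alpha_grid = seq(0.1, 0.9, 0.2),
                             beta_grid = seq(0.1, 0.9, 0.2)) {
  cfg <- load_config(config)
  grid <- expand.grid(alpha = alpha_grid, beta = beta_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg$plabgan$alpha <- grid$alpha[i]
    cfg$plabgan$beta <- grid$beta[i]
    ex <- run_experiment(cfg)
    tibble::tibble(alpha = grid$alpha[i], beta = grid$beta[i],
                   accuracy = ex$mean_accuracy, sd = ex$sd_accuracy)
  })
  structure(list(results = do.call(rbind, rows), config = cfg),
            class = "plabgan_sweep")
}

#' @export
print.plabgan_sweep <- function(x, ...) {
  best <- x$results[which.max(x$results$accuracy), ]
  cat(sprintf("<plabgan_sweep> %d settings; best accuracy %.4f at alpha=%.2g, beta=%.2g\n",
              nrow(x$results), best$accuracy, best$alpha, best$beta))
  invisible(x)
}

#' @export
tidy.plabgan_sweep <- function(x, ...) x$results

#' Plot a weight sweep as an accuracy heatmap
#'
#' @param object A `plabgan_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plabgan_sweep <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$alpha),
                                   y = factor(.data$beta),
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$accuracy)),
                       colour = "white") +
    ggplot2::labs(x = expression(alpha), y = expression(beta)) +
    ggplot2::theme_minimal()
}
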