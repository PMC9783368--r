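make_train_parts <- function(seed = 21) {
  pool <- make_synthetic_dataset(synth_spec(3, 12, 16, 1, 0.1, seed = seed))
  split_labelled_unlabelled(pool, 4, seed = seed + 1)
}

test_that("zero iterations return the seeded initialisation and empty traces", {
  parts <- make_train_parts()
  cfg <- plabgan_config(max_iterations = 0, seed = 5, latent_dim = 6,
                        gen_base_channels = 8, disc_widths = c(4, 8, 8))
  fit <- train_plabgan(parts$labelled, unlabelled = parts$unlabelled,
                       cfg = cfg)
  expect_equal(nrow(fit$trace), 0)
  # discriminator weights equal a fresh build under the same derived seed
  ref <- plabgan_discriminator(16, 1, 3, cfg$disc_widths, cfg$dropout,
                               seed = plabgan:::derive_seed(5L, 2L))
  expect_identical(fit$discriminator$net$layers[[11]]$par,
                   ref$net$layers[[11]]$par)
  ref_g <- plabgan_generator(16, 1, cfg$latent_dim, cfg$gen_base_channels,
                             seed = plabgan:::derive_seed(5L, 1L))
  expect_identical(fit$generator$net$layers[[1]]$par,
                   ref_g$net$layers[[1]]$par)
})

test_that("training is bit-reproducible under a fixed seed", {
  parts <- make_train_parts()
  cfg <- plabgan_config(max_iterations = 6, seed = 9, latent_dim = 6,
                        gen_base_channels = 8, disc_widths = c(4, 8, 8))
  ex <- train_feature_extractor(parts$labelled, epochs = 1, seed = 2)
  cent <- fit_centroids(extract_features(ex, parts$labelled),
                        parts$labelled$labels)
  pseudo <- pseudo_label_dataset(parts$unlabelled, ex, cent)
  f1 <- train_plabgan(parts$labelled, parts$unlabelled, pseudo, cfg)
  f2 <- train_plabgan(parts$labelled, parts$unlabelled, pseudo, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$discriminator$net$layers[[1]]$par,
                   f2$discriminator$net$layers[[1]]$par)
  expect_identical(f1$generator$net$layers[[1]]$par,
                   f2$generator$net$layers[[1]]$par)
})

test_that("loss components stay finite and nonnegative at every logged step", {
  parts <- make_train_parts(seed = 33)
  cfg <- plabgan_config(max_iterations = 8, seed = 4, latent_dim = 6,
                        gen_base_channels = 8, disc_widths = c(4, 8, 8))
  ex <- train_feature_extractor(parts$labelled, epochs = 1, seed = 2)
  cent <- fit_centroids(extract_features(ex, parts$labelled),
                        parts$labelled$labels)
  pseudo <- pseudo_label_dataset(parts$unlabelled, ex, cent)
  fit <- train_plabgan(parts$labelled, parts$unlabelled, pseudo, cfg)
  tr <- fit$trace
  for (col in c("l_label", "l_unlabel", "l_gen", "l_d", "g_loss")) {
    expect_true(all(is.finite(tr[[col]])), info = col)
    expect_true(all(tr[[col]] >= 0), info = col)
  }
  expect_equal(tr$l_d, tr$l_label + 0.5 * tr$l_unlabel + 0.5 * tr$l_gen)
})

test_that("with zero weights and batches disabled, training equals a plain supervised loop", {
  parts <- make_train_parts(seed = 8)
  lab <- parts$labelled
  cfg <- plabgan_config(alpha = 0, beta = 0, use_pseudo_labels = FALSE,
                        use_unlabelled = FALSE, use_generated = FALSE,
                        max_iterations = 10, seed = 13, batch_size = 8,
                        latent_dim = 6, gen_base_channels = 8,
                        disc_widths = c(4, 8, 8))
  fit <- train_plabgan(lab, cfg = cfg)

  # independent supervised cross-entropy loop sharing init and batch order
  disc <- plabgan_discriminator(16, 1, 3, cfg$disc_widths, cfg$dropout,
                                seed = plabgan:::derive_seed(13L, 2L))
  x <- aperm(lab$images, c(2, 3, 1, 4))
  y <- lab$labels
  opt <- plabgan:::adam_init(disc$net)
  old <- plabgan:::rng_scope_open(plabgan:::derive_seed(13L, 3L))
  losses <- numeric(10)
  for (it in 1:10) {
    il <- sample.int(dim(x)[3], 8, replace = TRUE)
    fwd <- plabgan:::net_forward(disc$net, x[, , il, , drop = FALSE],
                                 train = TRUE)
    disc$net <- fwd$net
    p <- class_probabilities(fwd$out)
    losses[it] <- plabgan:::ce_loss(p, y[il])
    bk <- plabgan:::net_backward(disc$net, fwd$caches,
                                 plabgan:::ce_grad(p, y[il]))
    up <- plabgan:::adam_step(disc$net, bk$grads, opt, cfg$lr,
                              b1 = cfg$adam_beta1)
    disc$net <- up$net
    opt <- up$state
  }
  plabgan:::rng_scope_close(old)

  expect_equal(fit$trace$l_d, losses, tolerance = 1e-12)
  for (i in c(1, 3, 6, 11)) {
    expect_equal(fit$discriminator$net$layers[[i]]$par,
                 disc$net$layers[[i]]$par, tolerance = 1e-12)
  }
})

test_that("early stopping halts on a validation plateau", {
  parts <- make_train_parts(seed = 12)
  cfg <- plabgan_config(alpha = 0, beta = 0, use_pseudo_labels = FALSE,
                        use_unlabelled = FALSE, use_generated = FALSE,
                        max_iterations = 40, seed = 2, eval_every = 5,
                        patience = 2, latent_dim = 6, gen_base_channels = 8,
                        disc_widths = c(4, 8, 8))
  fit <- train_plabgan(parts$labelled, cfg = cfg, val = parts$labelled)
  expect_lte(nrow(fit$trace), 40)
  expect_false(all(is.na(fit$trace$val_accuracy)))
})

test_that("invalid configurations and inputs are rejected", {
  expect_error(plabgan_config(alpha = -1), "alpha")
  expect_error(plabgan_config(lr = 0), "lr")
  expect_error(plabgan_config(batch_size = 0), "batch_size")
  empty <- new_dataset_for_tests(array(0, c(0, 16, 16, 1)))
  expect_error(train_plabgan(empty, cfg = plabgan_config(max_iterations = 1)),
               "non-empty")
})
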