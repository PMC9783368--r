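# A configuration small enough for fast orchestration tests.
tiny_config <- function(...) {
  base <- list(
    datagen = list(n_classes = 2L, n_per_class = 8L, image_size = 16L,
                   noise_sd = 0.1, n_labelled_per_class = 3L,
                   n_test_per_class = 4L),
    pseudolabel = list(epochs = 1L),
    plabgan = list(max_iterations = 3L, latent_dim = 6L,
                   gen_base_channels = 8L),
    seed = 5L)
  utils::modifyList(base, list(...))
}

test_that("malformed configurations are rejected with the offending keys", {
  expect_error(load_config(list(datagen = list(n_classs = 4))), "n_classs")
  expect_error(load_config(list(bogus_block = list())), "bogus_block")
  cfg <- load_config(list(datagen = list(n_classes = 5)))
  expect_equal(cfg$datagen$n_classes, 5)
  expect_equal(cfg$plabgan$alpha, 0.5)  # defaults fill the rest
})

test_that("YAML configurations load through the same path", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(datagen = list(n_classes = 3), seed = 9), path)
  cfg <- load_config(path)
  expect_equal(cfg$datagen$n_classes, 3)
  expect_equal(cfg$seed, 9)
})

test_that("a fixed-seed experiment is fully reproducible", {
  a <- run_experiment(tiny_config())
  b <- run_experiment(tiny_config())
  expect_identical(a$results, b$results)
  expect_identical(a$reports[[1]]$confusion_matrix,
                   b$reports[[1]]$confusion_matrix)
})

test_that("replicate aggregation equals the mean of per-repeat accuracies", {
  ex <- run_experiment(tiny_config(eval = list(repeats = 3L)))
  expect_equal(nrow(ex$results), 3)
  expect_equal(ex$results$seed, 5:7)
  expect_equal(ex$mean_accuracy, mean(ex$results$accuracy))
  expect_equal(ex$sd_accuracy, sd(ex$results$accuracy))
})

test_that("zero training iterations evaluate the seeded-init discriminator", {
  cfg <- tiny_config(plabgan = list(max_iterations = 0L, latent_dim = 6L,
                                    gen_base_channels = 8L))
  ex <- run_experiment(cfg)
  # rebuild the untrained discriminator along the same seed path
  full <- load_config(cfg)
  seed_r <- full$seed
  train_seed <- plabgan:::derive_seed(seed_r, 16L)
  defaults <- plabgan_config()
  disc <- plabgan_discriminator(16, 1, 2, defaults$disc_widths,
                                full$plabgan$dropout,
                                seed = plabgan:::derive_seed(train_seed, 2L))
  test <- make_synthetic_dataset(
    synth_spec(2, 4, 16, 1, 0.1, seed = plabgan:::derive_seed(seed_r, 13L)))
  expect_equal(ex$results$accuracy,
               evaluate(disc, test)$overall_accuracy)
})

test_that("experiment artifacts are persisted and sufficient to reproduce", {
  out <- withr::local_tempdir()
  ex <- run_experiment(tiny_config(), out = out)
  expect_true(file.exists(file.path(out, "config.yaml")))
  expect_true(file.exists(file.path(out, "run_manifest.json")))
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "trace.csv")))
  # the persisted config reproduces the run
  again <- run_experiment(file.path(out, "config.yaml"))
  expect_equal(again$results$accuracy, ex$results$accuracy)
})

test_that("the weight sweep evaluates every grid point", {
  sw <- sweep_alpha_beta(tiny_config(), alpha_grid = c(0.2, 0.8),
                         beta_grid = 0.5)
  expect_equal(nrow(sw$results), 2)
  expect_named(sw$results, c("alpha", "beta", "accuracy", "sd"))
  expect_true(all(sw$results$accuracy >= 0 & sw$results$accuracy <= 1))
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("the CLI simulates datasets and runs configured experiments deterministically", {
  dir <- withr::local_tempdir()
  st <- plabgan_cli(c("simulate", "--classes", "2", "--per-class", "3",
                      "--size", "16", "--noise", "0.1", "--seed", "4",
                      "--out", file.path(dir, "synth")))
  expect_equal(st, 0L)
  synth <- read_dataset(file.path(dir, "synth"))
  expect_equal(dim(synth$images)[1], 6)
  expect_true(file.exists(file.path(dir, "synth", "cli_manifest.json")))

  cfg_path <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(tiny_config(), cfg_path)
  o1 <- capture.output(
    plabgan_cli(c("run", "--config", cfg_path, "--out", file.path(dir, "r1"))))
  o2 <- capture.output(
    plabgan_cli(c("run", "--config", cfg_path, "--out", file.path(dir, "r2"))))
  expect_identical(o1, o2)
  expect_identical(readLines(file.path(dir, "r1", "results.csv")),
                   readLines(file.path(dir, "r2", "results.csv")))
  expect_identical(readLines(file.path(dir, "r1", "trace.csv")),
                   readLines(file.path(dir, "r2", "trace.csv")))
})
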