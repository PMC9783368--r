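test_that("generated datasets honour the counting and clipping contract", {
  data <- make_synthetic_dataset(synth_spec(4, 10, 32, 1, 0, seed = 1))
  expect_equal(dim(data$images), c(40, 32, 32, 1))
  expect_equal(as.vector(table(data$labels)), rep(10, 4))
  expect_true(all(data$images >= -1 & data$images <= 1))
  expect_setequal(unique(data$labels), 0:3)

  noisy <- make_synthetic_dataset(synth_spec(3, 5, 16, 3, 2, seed = 2))
  expect_true(all(noisy$images >= -1 & noisy$images <= 1))
  expect_equal(dim(noisy$images)[4], 3)
})

test_that("the same spec reproduces a bit-identical dataset", {
  for (sd in c(0, 0.3)) {
    a <- make_synthetic_dataset(synth_spec(4, 4, 16, 1, sd, seed = 9))
    b <- make_synthetic_dataset(synth_spec(4, 4, 16, 1, sd, seed = 9))
    expect_identical(a$images, b$images)
    expect_identical(a$labels, b$labels)
  }
})

test_that("class templates are pairwise distinct without noise", {
  data <- make_synthetic_dataset(synth_spec(6, 1, 32, 1, 0, seed = 1))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_gt(max(abs(data$images[i, , , ] - data$images[j, , , ])), 0)
    }
  }
})

test_that("within-class pixel variance at pattern-flat pixels matches the noise variance", {
  # independent sample-moment oracle over the generated arrays
  sd <- 0.1
  data <- make_synthetic_dataset(synth_spec(4, 100, 32, 1, sd, seed = 7))
  template <- plabgan:::class_template(0, 32, 1)
  flat <- abs(template[, , 1]) < 0.05   # noise never clipped there
  imgs <- data$images[data$labels == 0, , , 1]
  pixel_var <- apply(imgs, c(2, 3), stats::var)
  expect_equal(mean(pixel_var[flat]), sd^2, tolerance = 0.05)
})

test_that("invalid specs are rejected", {
  expect_error(synth_spec(n_classes = 1), "n_classes")
  expect_error(synth_spec(image_size = 7), "image_size")
  expect_error(synth_spec(n_per_class = 0), "n_per_class")
  expect_error(synth_spec(noise_sd = -1), "noise_sd")
  expect_error(synth_spec(channels = 2), "channels")
})

test_that("stratified splits are exact, disjoint, exhaustive and seeded", {
  data <- make_synthetic_dataset(synth_spec(4, 10, 16, 1, 0.1, seed = 5))
  parts <- split_labelled_unlabelled(data, 5, seed = 3)
  expect_equal(n_total <- dim(parts$labelled$images)[1], 20)
  expect_equal(dim(parts$unlabelled$images)[1], 20)
  expect_equal(as.vector(table(parts$labelled$labels)), rep(5, 4))
  # exhaustive + disjoint: hidden truth completes the class counts
  expect_equal(as.vector(table(c(parts$labelled$labels,
                                 unlabelled_truth(parts$unlabelled)))),
               rep(10, 4))
  again <- split_labelled_unlabelled(data, 5, seed = 3)
  expect_identical(parts$labelled$images, again$labelled$images)
  expect_identical(unlabelled_truth(parts$unlabelled),
                   unlabelled_truth(again$unlabelled))

  # boundary: full budget leaves the pool empty
  all_lab <- split_labelled_unlabelled(data, 10, seed = 1)
  expect_equal(dim(all_lab$unlabelled$images)[1], 0)

  expect_error(split_labelled_unlabelled(data, 11, seed = 1), "exceeds")
})

test_that("the unlabelled pool exposes no labels outside the sealed accessor", {
  data <- make_synthetic_dataset(synth_spec(3, 4, 16, 1, 0, seed = 2))
  parts <- split_labelled_unlabelled(data, 2, seed = 1)
  un <- parts$unlabelled
  expect_null(un$labels)
  expect_false("labels" %in% names(un)[!vapply(un, is.null, TRUE)])
  expect_length(unlabelled_truth(un), 6)
  expect_error(unlabelled_truth(parts$labelled), "no sealed truth")
})
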