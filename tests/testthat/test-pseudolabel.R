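test_that("centroids are per-class means (symmetry, identity, brute force)", {
  v <- c(1, -2, 3)
  m <- fit_centroids(rbind(v, -v, 2 * v, -2 * v), c(0, 0, 1, 1))
  expect_equal(m$centroids[1, ], rep(0, 3))
  expect_equal(m$centroids[2, ], rep(0, 3))

  single <- fit_centroids(rbind(c(1, 2), c(5, 9)), c(0, 1))
  expect_equal(single$centroids, rbind(c(1, 2), c(5, 9)))

  set.seed(2)
  f <- matrix(rnorm(30 * 4), 30)
  y <- sample(0:2, 30, replace = TRUE)
  y[1:3] <- 0:2  # ensure presence
  m3 <- fit_centroids(f, y)
  for (k in 0:2) {
    loop_mean <- numeric(4)
    cnt <- 0
    for (i in 1:30) if (y[i] == k) { loop_mean <- loop_mean + f[i, ]; cnt <- cnt + 1 }
    expect_equal(m3$centroids[k + 1, ], loop_mean / cnt)
  }
  expect_equal(m3$weights, rep(1, 4))
  expect_error(fit_centroids(f, rep(2, 30)), "present")
})

test_that("pseudo-label assignment matches identity, tie and exhaustive-scan oracles", {
  cent <- rbind(c(0, 0), c(3, 0), c(0, 3))
  m <- structure(list(centroids = cent, weights = c(1, 1), counts = c(1, 1, 1),
                      K = 3L), class = "centroid_model")
  at2 <- assign_pseudo_labels(m, rbind(c(0, 3)))
  expect_equal(at2$pseudo_labels, 2L)
  expect_equal(at2$distances[1, 3], 0)

  # equidistant from the first two centroids -> lowest class index
  tie <- assign_pseudo_labels(m, rbind(c(1.5, 0)))
  expect_equal(tie$distances[1, 1], tie$distances[1, 2])
  expect_equal(tie$pseudo_labels, 0L)

  set.seed(5)
  feats <- matrix(rnorm(200 * 7), 200)
  centK <- matrix(rnorm(5 * 7), 5)
  w <- runif(7, 0.1, 2)
  mk <- structure(list(centroids = centK, weights = w, counts = rep(1, 5),
                       K = 5L), class = "centroid_model")
  got <- assign_pseudo_labels(mk, feats)
  # brute-force double loop over classes and dimensions
  for (i in 1:200) {
    d <- numeric(5)
    for (k in 1:5) {
      for (j in 1:7) d[k] <- d[k] + w[j] * (feats[i, j] - centK[k, j])^2
    }
    expect_equal(got$pseudo_labels[i], which.min(d) - 1L)
    expect_equal(got$distances[i, ], d, tolerance = 1e-9)
    expect_equal(got$margin[i], sort(d)[2] - sort(d)[1], tolerance = 1e-9)
  }

  # scale invariance of the weights
  mk2 <- mk; mk2$weights <- 7.3 * w
  expect_equal(assign_pseudo_labels(mk2, feats)$pseudo_labels,
               got$pseudo_labels)
  expect_error(assign_pseudo_labels(mk, feats[, 1:3]), "dimension")
})

test_that("anchored K-means is a no-op at max_iter 0, fixed at its own centroids, and matches a reference Lloyd loop", {
  set.seed(9)
  f <- matrix(rnorm(20 * 2), 20)
  m <- fit_centroids(f, rep(0:1, each = 10))
  expect_identical(refine_kmeans(m, matrix(rnorm(10 * 2), 10), max_iter = 0), m)

  at_cent <- m$centroids[c(1, 2, 1, 2), ]
  fixed <- refine_kmeans(m, at_cent, max_iter = 1)
  expect_equal(fixed$centroids, m$centroids)

  # reference Lloyd with the same anchored pooling rule
  set.seed(31)
  X <- rbind(matrix(rnorm(30, -2), 15, 2), matrix(rnorm(30, 2), 15, 2))
  lab_f <- rbind(matrix(rnorm(10, -2), 5, 2), matrix(rnorm(10, 2), 5, 2))
  m2 <- fit_centroids(lab_f, rep(0:1, each = 5))
  got <- refine_kmeans(m2, X, max_iter = 5, tol = 0)
  cent <- m2$centroids
  for (it in 1:5) {
    d <- cbind(rowSums((X - matrix(cent[1, ], 30, 2, byrow = TRUE))^2),
               rowSums((X - matrix(cent[2, ], 30, 2, byrow = TRUE))^2))
    a <- apply(d, 1, which.min)
    for (k in 1:2) {
      pts <- X[a == k, , drop = FALSE]
      cent[k, ] <- (5 * m2$centroids[k, ] + colSums(pts)) / (5 + nrow(pts))
    }
  }
  expect_equal(got$centroids, cent, tolerance = 1e-12)
})

test_that("Lloyd iterations never increase the anchored within-cluster objective", {
  set.seed(77)
  for (trial in 1:10) {
    f <- matrix(rnorm(12 * 2), 12)
    m <- fit_centroids(f, rep(0:2, each = 4))
    X <- matrix(rnorm(60 * 2, sd = 2), 60)
    out <- refine_kmeans(m, X, max_iter = 8, tol = 0)
    sse <- attr(out, "sse")
    expect_true(all(diff(sse) <= 1e-9))
  }
})

test_that("the extractor trains, extracts deterministic features and validates inputs", {
  data <- tiny_dataset(K = 3, n = 8, size = 16, sd = 0.05, seed = 7)
  ex <- train_feature_extractor(data, epochs = 3, seed = 5)
  expect_gt(ex$trace$accuracy[3], 1 / 3)  # above chance

  f <- extract_features(ex, data)
  expect_equal(dim(f), c(24, ex$feature_dim))

  # duplicate image -> identical feature rows
  dup <- data$images[c(1, 1), , , , drop = FALSE]
  fd <- extract_features(ex, dup)
  expect_identical(fd[1, ], fd[2, ])

  # features of different class templates separate after training
  templ <- make_synthetic_dataset(synth_spec(3, 1, 16, 1, 0, seed = 1))
  ft <- extract_features(ex, templ)
  expect_gt(sqrt(sum((ft[1, ] - ft[2, ])^2)), 0)

  wrong <- array(0, c(2, 8, 8, 1))
  expect_error(extract_features(ex, wrong), "shape")

  one_class <- new_dataset_for_tests(data$images[data$labels == 0, , , ,
                                                 drop = FALSE],
                                     rep(0L, 8))
  expect_error(train_feature_extractor(one_class, epochs = 1), "2 classes")
})

test_that("extractor training is reproducible and epochs = 0 returns the seeded init", {
  data <- tiny_dataset(K = 2, n = 4, size = 16, sd = 0.1, seed = 3)
  e0a <- train_feature_extractor(data, epochs = 0, seed = 11)
  e0b <- train_feature_extractor(data, epochs = 0, seed = 11)
  expect_identical(extract_features(e0a, data), extract_features(e0b, data))
  expect_equal(nrow(e0a$trace), 0)

  e1a <- train_feature_extractor(data, epochs = 2, seed = 11)
  e1b <- train_feature_extractor(data, epochs = 2, seed = 11)
  expect_identical(extract_features(e1a, data), extract_features(e1b, data))
  expect_identical(e1a$trace, e1b$trace)
})
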