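test_that("resize_normalize maps an 8-bit image onto the target shape and range", {
  set.seed(1)
  img <- array(sample(0:255, 256 * 256, replace = TRUE), c(1, 256, 256, 1))
  out <- resize_normalize(img, target_size = 128, channels = 1,
                          source_range = c(0, 255))
  expect_equal(dim(out), c(1, 128, 128, 1))
  expect_gte(min(out), -1)
  expect_lte(max(out), 1)
})

test_that("a constant image at the range midpoint maps to zero", {
  img <- array(127.5, c(1, 32, 32, 1))
  out <- resize_normalize(img, 16, 1, source_range = c(0, 255))
  expect_equal(max(abs(out)), 0)
})

test_that("bilinear resize matches an independent per-pixel resampler", {
  # naive double-loop oracle under the same pixel-centre convention
  naive_bilinear <- function(x, n_out) {
    n_in <- nrow(x)
    out <- matrix(0, n_out, n_out)
    for (i in seq_len(n_out)) {
      for (j in seq_len(n_out)) {
        si <- min(max((i - 0.5) * n_in / n_out + 0.5, 1), n_in)
        sj <- min(max((j - 0.5) * n_in / n_out + 0.5, 1), n_in)
        i0 <- min(floor(si), n_in - 1); j0 <- min(floor(sj), n_in - 1)
        fi <- si - i0; fj <- sj - j0
        out[i, j] <- (1 - fi) * ((1 - fj) * x[i0, j0] + fj * x[i0, j0 + 1]) +
          fi * ((1 - fj) * x[i0 + 1, j0] + fj * x[i0 + 1, j0 + 1])
      }
    }
    out
  }
  checker <- matrix(c(0, 1, 0, 1,
                      1, 0, 1, 0,
                      0, 1, 0, 1,
                      1, 0, 1, 0), 4, 4, byrow = TRUE)
  got <- resize_normalize(array(checker, c(1, 4, 4, 1)), 2, 1,
                          source_range = c(0, 1))
  want <- 2 * naive_bilinear(checker, 2) - 1
  expect_equal(got[1, , , 1], want, tolerance = 1e-12)

  set.seed(4)
  r <- matrix(runif(64), 8, 8)
  got_r <- resize_normalize(array(r, c(1, 8, 8, 1)), 5, 1,
                            source_range = c(0, 1))
  expect_equal(got_r[1, , , 1], 2 * naive_bilinear(r, 5) - 1,
               tolerance = 1e-12)
})

test_that("channel conversion averages RGB and replicates grey", {
  rgb <- array(0, c(1, 8, 8, 3))
  rgb[, , , 1] <- 0.3; rgb[, , , 2] <- 0.6; rgb[, , , 3] <- 0.9
  grey <- resize_normalize(rgb, 8, 1, source_range = c(0, 1))
  expect_equal(unique(as.vector(grey)), 2 * 0.6 - 1, tolerance = 1e-12)
  back <- resize_normalize(grey, 8, 3, source_range = c(-1, 1))
  expect_equal(dim(back)[4], 3)
  expect_equal(back[, , , 1], back[, , , 3])
})

test_that("invalid preprocessing inputs are rejected", {
  img <- array(0.5, c(1, 8, 8, 1))
  expect_error(resize_normalize(img, 8, 1, source_range = c(1, 0)),
               "source_range")
  expect_error(resize_normalize(img, 8, 2), "channels")
  expect_error(resize_normalize("x", 8, 1), "array")
})

test_that("augmentation multiplies counts, preserves labels and the identity copy", {
  data <- tiny_dataset(K = 2, n = 5, size = 16, sd = 0.1, seed = 3)
  out <- augment(data, factor = 3, seed = 11)
  expect_equal(dim(out$images)[1], 30)
  expect_equal(out$labels, rep(data$labels, 3))
  expect_identical(out$images[1:10, , , , drop = FALSE], data$images)
  expect_true(all(out$images >= -1 & out$images <= 1))

  expect_identical(augment(data, factor = 1, seed = 5), data)
  expect_error(augment(data, factor = 0), "factor")

  twice <- augment(data, factor = 3, seed = 11)
  expect_identical(out$images, twice$images)
})

test_that("pure translation moves a bright pixel by exactly the shift", {
  img <- array(-1, c(9, 9, 1))
  img[5, 4, 1] <- 1
  shifted <- plabgan:::rotate_translate(img, deg = 0, dy = 0, dx = 2)
  pos <- which(shifted[, , 1] == max(shifted[, , 1]), arr.ind = TRUE)
  expect_equal(as.vector(pos), c(5, 6))
  # uncovered border reads as background
  expect_equal(max(abs(shifted[, 1:2, 1] + 1)), 0)
})
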