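# Shared fixtures, generated in code. Small sizes keep the default run fast;
# the heavier study-scale runs live in test-acceptance.R.

tiny_dataset <- function(K = 3L, n = 6L, size = 16L, sd = 0.05, seed = 42L) {
  make_synthetic_dataset(synth_spec(K, n, size, 1L, sd, seed))
}

# A quickly trained extractor on a small separable set.
tiny_extractor <- function(K = 3L, n = 8L, size = 16L, sd = 0.05,
                           epochs = 3L, seed = 7L) {
  data <- tiny_dataset(K, n, size, sd, seed)
  train_feature_extractor(data, epochs = epochs, seed = seed)
}

with_seed_for_tests <- function(seed, expr) plabgan:::with_seed(seed, expr)

# Deterministic images from explicit noise (inference mode).
generate_images_from_noise <- function(gen, z) {
  fwd <- plabgan:::net_forward(gen$net, z, train = FALSE)
  aperm(fwd$out, c(3, 1, 2, 4))
}

new_dataset_for_tests <- function(images, labels = NULL) {
  plabgan:::new_dataset(images, labels = labels,
                        n_classes = if (!is.null(labels)) {
                          max(labels) + 1L
                        } else NULL)
}

# Random valid (K+1)-probability matrix.
random_probs <- function(n, Kp1, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * Kp1), n)
  m / rowSums(m)
}
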