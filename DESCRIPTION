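Package: plabgan
Title: Semi-Supervised Medical Image Classification with Pseudo-Labelling and a K+1-Class GAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised image classification for settings where labelled
    medical images are scarce but unlabelled images are plentiful. A compact
    residual convolutional network is trained on the labelled pool, per-class
    feature centroids are fitted, and unlabelled images receive pseudo labels
    by nearest weighted-centroid assignment (with optional K-means refinement).
    A generative adversarial network is then trained whose discriminator is a
    (K+1)-way classifier (K real classes plus one synthetic class) under a
    weighted composite loss, with feature matching for the generator. Includes
    a seeded synthetic-image generator so the whole pipeline is testable
    without external data, evaluation reports, ggplot2 figures and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
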