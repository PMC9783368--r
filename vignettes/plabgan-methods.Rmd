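---
title: "Semi-supervised classification with pseudo-labelling and a K+1-class adversarial classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised classification with pseudo-labelling and a K+1-class adversarial classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Supervised image classifiers need labels; in medical imaging labels are the
expensive part. `plabgan` targets the regime of a *small* labelled pool
(tens to a few hundred images per class) beside a *large* unlabelled pool,
and uses the unlabelled images twice:

1. **As pseudo-labelled training signal.** A residual CNN trained on the
   labelled pool maps images to feature vectors; each class i is summarised
   by its centroid x̄ᵢ (mean feature vector). An unlabelled image x gets the
   pseudo label

   $$\mathrm{label}(x) = \arg\min_i \sum_d w_d\,\big(f_d(x) - \bar{x}_{i,d}\big)^2 ,$$

   the nearest centroid under weighted squared Euclidean distance. The
   weights default to all ones (plain Euclidean); any nonnegative vector
   may be supplied, and the assignment is invariant to its overall scale.

2. **As a density signal in an adversarial game.** The discriminator D is a
   (K+1)-way classifier — K real classes and one synthetic class. Softmax
   probabilities come from the K+1 logits; three loss terms combine as

   $$l_d = l_{label} + \alpha\, l_{unlabel} + \beta\, l_{gen},$$

   with $l_{label} = -\mathrm{E}\,\ln p(y\mid x)$ on labelled (and, weighted by
   a confidence factor, pseudo-labelled) images, $l_{unlabel} =
   -\mathrm{E}\,\ln(1 - p(y = K{+}1 \mid x))$ on unlabelled images, and
   $l_{gen} = -\mathrm{E}\,\ln p(y = K{+}1\mid x)$ on generated images. With
   $\alpha = \beta = 0$ and the extra batches disabled the loop reduces —
   step for step, bit for bit — to plain supervised cross-entropy training;
   the test suite asserts this equivalence against an independent training
   loop.

The generator is trained alternately with D frozen. Its default objective
is **feature matching**: the squared distance between batch-mean
flatten-layer activations of D on real versus generated batches. Matching
first-moment feature statistics rather than maximising the fooling
probability is the standard mitigation for mode collapse in this family of
models; the classic adversarial objective ($-\mathrm{E}\ln(1-p_{K+1})$ on
generated samples) is available as `generator_loss_mode = "adversarial"`.

## Architectures

* **Feature extractor** — CIFAR-style residual stack of depth 6n + 2:
  a 3×3 stem at 16 filters, three stages of n residual blocks at widths
  16/32/64 with stride-2 stage transitions and 1×1 projection shortcuts,
  batch norm + ReLU throughout, global average pooling, K-way dense head.
  Depth 20 (n = 3) is the classic configuration; the synthetic study runs
  use depth 8 (n = 1), which is already at ceiling on 32×32 inputs.
  Pretrained initial weights can be restored from a checkpoint, but the
  default trains from scratch: no portable pretrained weights exist for
  this architecture, and the compact stack trains in seconds at study
  scale.
* **Generator** — dense layer from a standard-normal latent vector
  (default length 100) reshaped to (size/4, size/4, 256); a transposed-conv
  block (stride 2, batch norm, LeakyReLU 0.01); a final transposed-conv
  (stride 2) with Tanh. At the 128×128×1 clinical configuration the
  reshape is exactly 32×32×256 and the output 128×128×1. Two deliberate
  design choices: the deconvolution kernel is
  4×4 with padding 1 (exact 2× upsampling, no checkerboard artifacts), and
  there is **no batch norm immediately before the Tanh output** — batch
  norm there fights the output range; this follows universal DCGAN
  practice.
* **Discriminator** — three 3×3 stride-2 conv blocks at widths 32/64/128
  (LeakyReLU 0.01; batch norm on blocks 2 and 3 only), flatten, dropout
  (rate 0.4, exposed), dense to K+1 logits. At 128×128×1 the block outputs
  are 64×64×32, 32×32×64 and 16×16×128, asserted exactly in the tests.

There is no deep-learning framework in the dependency stack: convolution
(im2col + BLAS matmul), transposed convolution (implemented by duality as
the data-gradient of a convolution), batch norm, dropout, the residual
blocks and Adam are implemented in the package and verified against
numerical differentiation. One inner loop — the col2im scatter-add of the
convolution data gradient — is compiled (Rcpp); everything else is base R.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha`, `beta` | 0.5, 0.5 | weights on the unlabelled / generated loss terms; 0.5 is the sweet spot of the grid sweep protocol (`sweep_alpha_beta()`) |
| `lr` | 1e-4 | Adam learning rate for both networks |
| `batch_size` | 16 | size of *each* sub-batch (labelled, pseudo, unlabelled, generated) |
| `adam_beta1` | 0.5 | Adam first-moment decay; the adversarial-training convention ("momentum 0.5"), second moment 0.999 |
| `pseudo_weight` | 1.0 | confidence weight on the pseudo-labelled cross-entropy term |
| `margin_threshold` | 0 | pseudo-labels with margin (second-best minus best distance) below this are dropped; 0 keeps all |
| `latent_dim` | 100 | generator noise length |
| `dropout` | 0.4 | discriminator dropout after flatten |
| `patience` | Inf | early stop after this many validation checks without improvement; Inf = fixed iteration budget |

Natural logarithms are used in every loss term (the base-2 variants differ
only by a constant absorbed into the learning rate), and every $-\ln(\cdot)$
clamps its argument at $10^{-12}$ so losses stay finite.

## Batch composition and randomness

Each iteration draws equal-sized sub-batches (equal sizes keep every
term's gradient scale comparable) and forwards them separately, so each population sees its own
batch-norm statistics. All randomness — initialisation, batch indices,
noise, dropout masks — flows from one integer seed through a scoped RNG
whose draw order is fixed and whose state never leaks into the caller's
session; a repeated run reproduces its report bit for bit. Pseudo-labelled
images enter the classification term under their pseudo labels *and* the
unlabelled pool still feeds the realness term; `use_pseudo_labels = FALSE`
recovers the plain semi-supervised ablation, which differs from the full
method only by pseudo-labelling.

## Pseudo-labelling modes

The default is pure nearest-centroid assignment to the labelled class
means (`refine_iter = 0`). Anchored K-means refinement is available: each
Lloyd iteration assigns unlabelled features to the nearest centroid and
recomputes centroid i as the mean of its assigned points *pooled with the
labelled class mean weighted by the labelled class count* — the labelled
evidence anchors each cluster so refinement cannot drift a cluster away
from its class. The anchored objective (assigned distances plus
count-weighted anchor displacement) is non-increasing across iterations,
which the tests assert on random problems. Distance ties break toward the
lowest class index, a fixed deterministic rule.

## The synthetic study design

The generator emulates the *structure* of a clinical semi-supervised
corpus, not its appearance: K visually distinct classes (oriented
Gabor-like gratings under class-specific Gaussian envelopes, pairwise
distinct by construction), additive Gaussian pixel noise on the [-1, 1]
scale as the separability knob, a small stratified labelled pool and a
large unlabelled pool whose true labels are retained only in a sealed
evaluation accessor. The benchmark configuration used in the tests and the
acceptance script — 4 classes, 32×32 pixels, noise sd 0.1, 10 labels per
class beside 400 unlabelled images, 300 training iterations, networks at
reduced width (latent 64, generator base 64) — runs in minutes on one CPU
core and was fixed once as the scaled-down analogue of the study design.

What passing these tests shows — and what it does not: the pipeline's
mechanics (losses, gradients, assignment rules, determinism, the ordering
full method ≥ ablations) are verified, but the synthetic classes are far
more separable than real radiographs or histopathology; at the benchmark
conditions all three arms reach 100% test accuracy, so the semi-supervised
*gain* observed on real corpora appears here only as a non-strict
ordering. Pixel noise, not anatomy, is the only nuisance factor; domain
shift, label noise and class imbalance are absent by design.

## Numerical choices and degenerate inputs

* Softmax uses max-subtraction; probability mass is conserved to 1e-6 and
  non-finite logits are rejected.
* Bilinear resize uses the pixel-centre convention, clamped at borders;
  augmentation pads uncovered regions with −1, the normalised black level.
* Augmentation copy 0 is always the identity, so `factor = 1` is exact.
* `max_iterations = 0` returns the seeded initialisation with empty traces;
  an empty labelled set, single-class training input, mismatched shapes and
  malformed configurations raise explicit validation errors (unknown YAML
  keys are named).
* Labelled/test pool sizes are configured as explicit per-class counts
  rather than split ratios: counts are unambiguous and map directly onto
  the labelled-budget design.

## Known limitations

* CPU-scale only: the engine is tuned for the study sizes above; 128×128
  training at clinical iteration counts is out of scope (the shape
  contracts at that configuration are still asserted).
* No conditional generation, minibatch discrimination or spectral
  normalisation; feature matching is the only stabiliser.
* Per-class accuracy is reported as within-class recall plus a one-vs-rest
  binary accuracy; threshold-based metrics (AUROC etc.) are not provided.
* Pseudo-label errors propagate into training by design; the margin
  threshold is the provided mitigation, off by default.
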