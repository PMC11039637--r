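---
title: "Methods: architecture-searched lesion segmentation and incremental classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: architecture-searched lesion segmentation and incremental classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lesionforge)
```

# Overview

`lesionforge` implements a complete desk-scale workflow for dermoscopic
skin-lesion analysis:

1. **Preprocessing** — bilinear resizing, colour-space conversion,
   morphological hair removal, adaptive median filtering, adaptive local
   noise reduction, and contrast-limited adaptive histogram equalisation
   (CLAHE).
2. **Segmentation** — a fully convolutional encoder–decoder network
   (FCEDN) whose tunable architecture is described by a flat 22-gene
   hyperparameter vector, searched by the sparrow search algorithm
   (SpaSA) under a smoothed Jaccard fitness.
3. **Classification** — an incrementally growable Tree-CNN whose nodes
   are small adaptive CNNs, with copy-and-branch weight sharing and
   per-node label-transform bookkeeping.

A seeded synthetic dermoscopy generator makes all of this testable
without external data.  Every component is deterministic given its seed.

# The segmentation model

## Architecture encoding

The FCEDN is an encoder of convolution(+relu) layers, max-pooling layers
and a dropout layer, mirrored by transposed convolutions, unpooling
layers and a decoder dropout, closed by a 1×1 sigmoid output layer.  The
defining property is spatial symmetry: the output probability map always
has exactly the input's height and width.

The default composition is 4 convolutions / 2 pools / 1 dropout per
half.  Its tunable fields form a vector of length 22: 8 kernel counts,
8 kernel sizes, 4 pool strides, and 2 drop rates.  Gene bounds:

| field        | bounds     | type       |
|--------------|-----------|------------|
| kernel count | [20, 200] | integer    |
| kernel size  | [3, 5]    | integer    |
| pool stride  | [2, 3]    | integer    |
| drop rate    | [0.2, 0.4]| continuous |

Decoding rounds integer genes to the nearest integer and clips all genes
to their bounds, so any real-valued position decodes to a valid
architecture.  Two notes on the bounds:

* Pool strides are bounded [2, 3] (the field-standard pooling factors).
  Applying the convolution kernel range 3–5 to pooling strides would
  make almost every random genome spatially infeasible, because feature
  maps must stay divisible by the pooling product.
* Spatial feasibility itself (pool product equal to unpool product and
  dividing the input size) is handled during fitness evaluation by
  projecting the four pool/unpool genes to the nearest feasible
  configuration — standard constraint projection for metaheuristics.
  For power-of-two image sizes this effectively fixes the strides at 2;
  `build_network()` itself stays strict and rejects infeasible
  combinations with an informative error.

The structural layout places the two encoder pools immediately after
the first and second convolutions (and mirrors that in the decoder), so
most convolution work happens at reduced resolution; this is what makes
architecture search affordable on a single CPU.

## Training

Networks are trained with Adam (default learning rate `1e-3`, chosen so
that the light default architecture converges on separable synthetic
data within a handful of epochs) on the loss `1 − J_ε`, where

`J_ε = (ε + Σ p·y) / (ε + Σ y + Σ p − Σ p·y)`

is the smoothed Jaccard coefficient between the predicted probability
map `p` and the binary mask `y`.  Training the exact quantity that the
architecture search maximises keeps the two stages consistent.

The smoothing constant ε defaults to 1.0.  A randomised ε (anywhere in
(0, 1)) would make fitness non-deterministic and runs irreproducible, so
a fixed value is used; it is configurable via `fitness_context()` and
`fcedn(..., eps = )`.

The convolution engine is written with RcppArmadillo: pixel-major
im2col plus single-precision BLAS gemm for the forward and backward
passes.  There is no deep-learning framework dependency.

## Fitness and the search

`evaluate_fitness()` decodes a genome, builds the network, trains it on
the context's training images, and returns the **sum** over evaluation
images of the smoothed Jaccard between predicted and true masks (a sum,
not a mean, so the value scales with the evaluation-set size; the set
size is recorded alongside).  Evaluations are memoised by the rounded
integer genome so identical architectures are never retrained.

The sparrow search algorithm maintains a population of positions.  Per
iteration:

* **Producers** (the fittest `producer_fraction`) drift multiplicatively
  (no alarm) or take a Gaussian step (alarm raised, probability
  `1 − safety_threshold`).
* **Scroungers** (the rest) follow the best position: the worse half
  jump into its neighbourhood with per-gene Gaussian magnitudes, the
  better half contract halfway towards it with sparse random signs —
  genes not selected copy the anchor exactly, so single-gene refinements
  survive.
* **Scouts** (a random `scout_fraction`) take danger-response steps
  around the best position; half the time they probe a ±1 lattice
  neighbour of one integer gene (a mixed-integer adaptation that gives
  exact integer convergence).

Implementation choices that matter and why:

* Updates operate on per-gene **normalized coordinates** in [0, 1].
  The raw space is badly scaled (kernel counts span 180 units, drop
  rates 0.2), so raw-space step rules either freeze some genes or
  teleport others.
* All follower moves anchor on the **elitist best-ever record**, and the
  best-ever position is reinserted over the current worst after each
  evaluation sweep.  Without this the producers' multiplicative drift
  degrades the anchor every iteration and the population chases a
  corrupted target.
* The whole population is evaluated once per iteration, after the three
  update phases (ranks within an iteration use the previous sweep's
  fitness).

Verified behaviour: the 5-dimensional sphere optimum is reached to
within 1e-2 on 10/10 seeds (population 30, 100 iterations); a planted
22-gene architecture is recovered with all integer genes exact on 10/10
seeds (200 iterations); exhaustive search is matched on fully
enumerable 2-gene spaces.

# The preprocessing stack

Default order: resize → colour conversion → hair removal → adaptive
median → adaptive local filter → CLAHE.  Every step preserves the
[0, 255] intensity range and never alters mask values (resize's
nearest-neighbour resampling excepted).

A deliberate design contract of the stack is **re-processing
stability**: running the full default pipeline on an already-processed
noise-free image changes mean intensities by less than ±3 levels.  This
matters in practice (datasets get re-preprocessed by accident or by
design) and several defaults below were chosen to honour it:

* **CLAHE** (`equalize_adaptive()`) is implemented in-package: per-tile
  histograms (32 bins, tiles of at least 32 px), clip-limited with
  *water-filling* redistribution (excess mass goes only into below-cap
  bins, so the mapping slope never exceeds the clip limit), and
  bilinear interpolation between tile mappings.  It is applied to the
  HSV value channel with the colour channels rescaled by the value
  gain, which by construction cannot leave the [0, 255] gamut.  The
  default clip limit is **1.3**: clipped equalisation is only
  idempotent in the limit of no clipping, and at the conventional 2.0
  the enhancement re-amplifies texture that the denoising stages then
  remove, so repeated preprocessing would drift by ~8 intensity levels
  per pass.  Users who prefer stronger enhancement over re-processing
  stability can set `clahe_clip_limit = 2` explicitly.
* **Adaptive median** (`filter_adaptive_median()`) follows the classical
  two-stage algorithm (window growing from 3 to `median_max_window`),
  with two robustness guards on the impulse decision: the deviation
  from the window median must exceed `impulse_margin` (default 40 —
  salt-and-pepper values sit 60–250 levels from the local median) *and*
  5× the window's median absolute deviation (a Hampel-style rule, so
  pixels of legitimately high-contrast texture are not rewritten).
  `impulse_margin = 0` restores the textbook behaviour.
* **Adaptive local filter** (`filter_adaptive_local()`):
  `out = x − (σ²_noise/σ²_local)(x − μ_local)` with the ratio clipped
  to [0, 1].  The `"auto"` noise estimate uses the Laplacian-difference
  operator (white noise passes it, low-frequency structure cancels), so
  an already-denoised image yields a near-zero estimate and the filter
  approaches the identity.  A median-of-local-variances estimate was
  rejected because it mistakes texture for noise and keeps smoothing on
  every pass.
* **Hair removal** (`remove_hairs()`) is the DullRazor-style morphology:
  a black-hat transform over a bank of oriented line structuring
  elements (length `hair_kernel_length`, 6 orientations), followed by
  inpainting from the morphological closing.  Detections are filtered
  by stroke geometry only — a component must be long (≥ 2.6× the kernel
  length) and narrow along its run (responding to a half-length line
  bank) — because any darkness criterion breaks on contrast-stretched
  images.  When a hair touches a wide dark structure and merges with it
  into one component, only the narrow pixels are inpainted.
* **Colour conversions** use `grDevices` (`rgb2hsv`, `convertColor`);
  HSV and Lab channels are rescaled into [0, 255] so the range contract
  holds in every representation.

# The synthetic generator

`generate_lesion()` composes, in order: a lighter textured skin
background (base ≈ (205, 170, 155) with low-frequency texture), a darker
roughly elliptical lesion whose border is perturbed by a low-order
radial Fourier series (harmonics 2–5, amplitudes up to 0.08), optional
dark curvilinear hair strokes (random cubic Bézier curves, 1–3 px wide,
intensity ≤ 60), then impulse (salt-and-pepper) and multiplicative
speckle noise on the full composite.  The lesion scale is found by
bisection so the mask hits the requested foreground fraction almost
exactly.  Each stage draws from its own derived seed, so the mask is
bit-identical across images that differ only in hair or noise settings
— the paired-generation oracle used by the hair-removal tests.

`class_id` selects the lesion colour from a fixed six-colour palette
(dark brown, reddish, blue-grey, tan, near-black, pink), so classifier
experiments have visually separable classes.  Note that some palette
pairs (e.g. dark brown vs near-black) are deliberately similar;
classifier tests use well-separated pairs.

What the generator does **not** emulate: real lesion pathology
(asymmetry classes, pigment networks, globules), camera vignetting and
colour casts, gel-interface artifacts, rulers and markers, and realistic
hair density.  Tests passing on this generator demonstrate that the
algorithms implement their contracts — not that the trained models would
transfer to clinical dermoscopy data.

# The Tree-CNN classifier

Each node of the tree is an adaptive CNN: convolution(+relu)(+batch
normalisation) + max-pool blocks, flatten, dropout, a dense layer, and a
softmax output — one output per child.  Leaves carry exactly one global
class.  Classification descends from the root by argmax softmax.

Incremental growth (`grow_tree()`): for each new class, the average
softmax of a seeded 10% sample under the node's classifier is computed
per child.  If the best affinity exceeds the add-to-child criterion
(default `2 / (n_children + 1)`, a scale-aware threshold: twice the
uniform probability under the grown output count), the class is routed
into that child — a leaf child becomes a branch over the old and new
class, a branch child absorbs the class one level down (tree depth is
capped at 2 by default, configurable).  Otherwise the class becomes a
new child.  When several children pass the criterion, the one with the
higher average softmax wins; exact ties are broken by a seeded random
choice.  Each node keeps a `labels_transform` lookup table (global class
→ local output index); composing the tables along any root-to-leaf path
is verified invertible after every grow.

Retraining touches only affected nodes: the root (which must learn the
enlarged routing task) and any branch that received a class.  All other
nodes keep bit-identical weights.  Nodes whose output count grew are
warm-started by `copy_and_branch()`: shared-layer weights are copied and
new randomly initialised output units appended, which preserves the old
classes' logits exactly until retraining.  Training images are retained
at the leaves so affected nodes can be retrained on all classes beneath
them — the price of incremental growth without a replay-free continual
learning method.

At this package's desk scale the warm-start advantage is measurable but
modest: across 10 paired seeded runs the copied model reached 95%
training accuracy at least as fast as a from-scratch model in 7, with a
mean advantage of ~0.6 epochs.

# Pipeline, problem sizes and reproducibility

`run_pipeline()` executes the configured stages and writes per-stage
artifacts plus manifests carrying the seed and a hash of the
configuration.  A run is a pure function of (config, seed); two runs
with identical config and seed produce byte-identical metric tables.

Default desk-scale sizes (all configurable): 60 synthetic 64×64 images
split 80/10/10; architecture search with population 5 and 3 iterations,
each fitness evaluation training on at most 12 images for 5 epochs; a
final model trained for 5 epochs on the full training split.  These
sizes complete in roughly ten minutes on one CPU core while leaving the
search enough signal to beat the all-background baseline by a wide
margin (mean test Jaccard ≈ 0.9 vs 0 at ε = 0).  The classifier
experiments use 32×32 images, two-block CNNs and 8 training epochs.

Numerical details worth knowing:

* Convolution gemms run in single precision; gradients match a slow
  double-precision reference to ~1e-5 relative, which is far below the
  noise floor of stochastic training.
* The fitness of an architecture whose decode, build, or training fails
  (or returns a non-finite value) is recorded as −∞ and the search
  continues.
* Thresholding of probability maps uses `>=`, so `threshold = 1` keeps
  pixels whose probability is exactly 1 and `threshold = 0` selects
  everything.
* Undefined metrics (zero denominators) raise classed errors rather than
  returning silent zeros; the single documented exception is the
  Matthews correlation with a zero marginal, which returns 0 with a
  warning.

# Known limitations

* The synthetic generator's simplicity means segmentation is an easy
  task; architecture search improves the fitness but the search
  landscape is shallow compared to real dermoscopy benchmarks.
* The engine has no GPU path and no batch-level vectorisation across
  images; large kernel counts (near the 200 bound) are slow to train.
* Unpooling is nearest-neighbour upsampling by the stored pool stride;
  max-pooling switch indices are not forwarded to the decoder.
* Skip connections, batch normalisation in the segmenter, multi-class
  segmentation and pretrained encoders are out of scope.
* The Tree-CNN stores training images at its leaves; memory grows with
  the class set.
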