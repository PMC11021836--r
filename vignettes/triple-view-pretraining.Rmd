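---
title: "Triple-view self-supervised pretraining: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple-view self-supervised pretraining: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`triview` pretrains an image encoder from unlabelled data by alignment of
multiple augmented views, in the Siamese, negative-pair-free family of
self-supervised methods. Each source image $x$ is passed three times
through a stochastic augmentation module $A$, giving views $x_1, x_2, x_3$.
A single parameter set — encoder $E$, projection MLP $P$, prediction MLP
$H$ — is applied to every view:

$$v_i = P(E(x_i)), \qquad z_i = H(P(E(x_i))).$$

Alignment of a prediction with a projection target is measured by negative
cosine similarity,

$$N(z, v) = -\frac{z}{\lVert z\rVert_2}\cdot\frac{v}{\lVert v\rVert_2},$$

and the training loss couples every ordered pair of distinct branches:

$$L = \frac{1}{3}\Big[\tfrac12 N(z_1, v_2) + \tfrac12 N(z_2, v_1)
      + \tfrac12 N(z_1, v_3) + \tfrac12 N(z_3, v_1)
      + \tfrac12 N(z_2, v_3) + \tfrac12 N(z_3, v_2)\Big],$$

with a **stop-gradient** on every projection target $v_j$: targets are
constants under differentiation, and only the prediction side
backpropagates. The stop-gradient is what prevents the trivial solution in
which all outputs collapse to one constant vector; the prediction MLP
absorbs the cross-view expectation that the per-draw views only sample.
For batches the loss is the mean of per-image losses.

Two numerical decisions deserve a note:

* **Normalization.** The six half-weighted terms sum to a quantity with
  infimum $-3$; the implementation divides by 3 (the number of unordered
  view pairs) so the documented minimum of $-1$ holds. Rescaling a loss by
  a positive constant only rescales gradients; both the normalized value
  and the raw sum (attribute `"raw"`) are exposed so loss curves can be
  compared on either convention.
* **Which side is stopped.** The implementation stops gradients on the
  projection targets $v$ (the convention of the closest prior Siamese
  methods); the prediction side $z$ is the live path. `triloss_gradient()`
  makes the contract inspectable: with `stop_targets = TRUE` the $v$-side
  gradients are exactly zero, and the $z$-side matches central finite
  differences (`triloss_gradient_check()`).

Norms below $10^{-8}$ raise an error (the direction of a near-zero vector
is meaningless); an epsilon of $10^{-12}$ under the square root guards the
well-conditioned path.

## Augmentation module

One view is produced by, in order: random resized crop, resize to
`out_size`, colour jitter, random greyscale, Gaussian blur, horizontal
flip, vertical flip. Defaults: crop scale 0.08–1.0; colour jitter with
probability 0.8 (brightness factor $1 \pm 0.32$, contrast and saturation
0.68–1.32, hue shift $\pm 0.02$); greyscale with probability 0.2; blur std
drawn uniformly from 0.1–2.0 px; both flips with probability 0.5.

Choices made where the recipe under-determines the implementation:

* **Aspect ratio** of the crop uses the conventional $[3/4, 4/3]$
  log-uniform range of every reference augmentation stack.
* **Blur probability** defaults to 1 (the blur step is always applied),
  reading the pipeline as strictly sequential; `blur_p` is configurable
  for asymmetric-blur experiments.
* **Brightness 0.32** is interpreted as the factor range $[0.68, 1.32]$,
  mirroring the printed contrast/saturation ranges.
* The four colour operations run in a **random order** per call, the
  standard convention.
* The blur kernel is truncated at radius $\lceil 4\sigma\rceil$ (odd total
  size) with **edge-repeating reflective padding**, so a constant image
  and the total pixel intensity are preserved exactly.
* Pixels are channel-last float arrays in $[0,1]$ with 1-based indexing;
  resizing is bilinear with half-pixel centres, making a same-size resize
  the exact identity. These conventions are fixed so tests can assert
  bit-exact reproducibility.
* **Seeding.** All randomness flows from explicit stream objects
  (`rng_stream()`); per-image, per-view substreams are derived by an
  integer mixing scheme (`rng_substream()`), so no execution-order or
  parallelism effect can reorder draws. Identical (image, config, seed)
  gives a bit-identical view triplet.

## Architecture

The default encoder is ResNet-50 with the classification head removed and
global average pooling, yielding 2048-dimensional features. The projection
MLP has three dense layers of width 8192, the first two followed by batch
normalization and ReLU, the last by batch normalization only. The
prediction MLP is a bottleneck: dense $8192 \to 2048$ with batch
normalization and ReLU, then dense $2048 \to 8192$ with nothing after it.
All three printed widths are asserted by forward-pass shape checks in the
test suite. "Each of these layers is 8192-dimensional" is read literally:
all three projection layers share the width.

* **Backbone initialisation** defaults to random (He) weights. Initialising
  from ImageNet weights is supported through
  `model_config(pretrained_backbone = TRUE)` plus a weights file, but no
  weights are bundled: the package must be self-contained and buildable
  offline.
* **Batch normalization** uses batch statistics in training mode and
  running statistics (momentum 0.1, epsilon $10^{-5}$) in evaluation mode;
  training mode requires batch size $\ge 2$.
* The `"tinycnn"` backbone (three conv–BN–ReLU stages with stride-2
  downsampling, then global average pooling; configurable feature width)
  exists so the whole pipeline trains in seconds on a CPU. It is test
  scaffolding, not part of the reference recipe.

The three branches *share* one parameter set — `forward_triplet()` applies
the same weights to all views, and the parameter count of the triple-branch
model equals that of a single branch.

All layers are implemented in base R with explicit forward and backward
passes (im2col convolution via BLAS matrix multiplication); the gradient of
every layer type is verified against central finite differences in the
test suite.

## Pretraining loop

SGD with momentum 0.9 and weight decay $5\times10^{-4}$; the learning rate
starts at 0.05 and follows a cosine decay,
$\eta_t = \eta_0\,\tfrac12(1 + \cos(\pi t/T))$, advanced **per step** (the
schedule is smooth and testable in closed form). Reference defaults:
$256\times256$ inputs, 200 epochs, batch size 256, projection width 8192,
latent width 2048. Deviations chosen where the recipe is silent:

* The base learning rate is used literally at any batch size; an opt-in
  flag applies linear scaling by `batch_size / 256`.
* Weight decay applies to all parameters, including batch-norm scale/shift
  and biases, matching the reference implementations of the closest prior
  method.
* A partial final batch is kept unless it has a single image, in which
  case it is dropped with a warning (batch normalization needs $\ge 2$).
* With augmentation ablated the three views coincide; the implementation
  then runs one forward pass and one backward pass with the summed
  branch gradients, which is algebraically identical because
  backpropagation is linear in the output gradient for fixed activations.

### Collapse diagnostic

`collapse_metric()` $\ell_2$-normalizes the batch of projections, takes the
per-dimension standard deviation across the batch, and averages over
dimensions: 0 iff the representation has fully collapsed, about
$1/\sqrt d$ for isotropically spread vectors. The non-collapse check in
the acceptance suite requires the metric to stay above $0.25/\sqrt d$ — a
quarter of the isotropic value — throughout training: far above numerical
noise, far below full isotropy, and not sensitive to the exact batch.

### Predictor gap

`predictor_gap()` reports the mean of $\lVert H(v_i) - v_j\rVert_2^2$ over
the three cyclic ordered branch pairs $(1,2), (2,3), (3,1)$ and the batch.
It quantifies how well the predictor has learned the cross-view
expectation. The raw quantity scales with $\lVert v\rVert^2$, which grows
during pretraining, so the raw gap of a trained model can exceed that of a
random one even as alignment improves; for before/after comparisons use
`relative = TRUE`, which divides by the mean squared target norm and does
decrease under pretraining on the desk-scale runs. (The pair set is a
choice: any fixed set of distinct ordered pairs measures the same quantity
up to symmetry.)

## Synthetic test-bed data

`synthetic_spec()` / `generate_dataset()` produce a deterministic
multi-class RGB dataset standing in for a class-per-folder medical-image
corpus. Class identity is encoded redundantly in three factors: base hue
(default evenly spaced, $\ge 0.2$ apart so default-strength colour jitter
cannot swap classes), sinusoidal texture frequency, and elliptical blob
count. Redundant, augmentation-stable signal is the point: hue and texture
survive crops and flips, which is exactly the precondition under which
view-alignment pretraining can work, so tests pass for the right reason.
Gaussian pixel noise (default $\sigma = 0.05$) keeps the task non-trivial
for a probe trained on a handful of labels.

What the generator does **not** emulate: stain variation, cell morphology,
class imbalance, label noise, resolution heterogeneity, or any
photorealistic structure. Green results on synthetic data demonstrate that
the machinery (augmentation, loss, optimisation, evaluation protocol) is
correct and that pretraining extracts augmentation-invariant signal — they
are not evidence about accuracy on real blood-smear or histopathology
images.

PNG is used for folder round-trips because it is lossless at 8 bits.

## Evaluation protocol

`split_dataset()` holds out a stratified 20% test set, then splits the
training portion into a labelled fraction (`labelled_ratio`) and an
unlabelled remainder, by largest-remainder allocation so the totals are
exactly $\lfloor 0.2n \rfloor$ and `round(ratio * n_train)`. Stratification
prevents empty classes at 1% labels on small datasets; a class too small
to stratify raises an error naming it.

The downstream classifier is the pretrained encoder, dropout 0.2, one
dense layer and softmax; projection and prediction MLPs are discarded.
`linear_probe()` freezes the encoder (its weights are bit-identical before
and after — asserted in tests); `fine_tune()` trains end to end. The
distinction is kept although parts of the protocol's description use
"fine-tuning a linear classifier" for both; a frozen run is always
available via `linear_probe()`. Head training uses cross-entropy, SGD with
momentum 0.9 and cosine decay over 30 epochs at learning rate 0.1 — chosen
once as the smallest budget at which the head reliably converges on
desk-scale feature sets; all are arguments.

Metrics come from the confusion matrix: accuracy is trace over total;
precision, recall and F1 are computed per class one-vs-rest and
**macro-averaged** (micro averaging is available via a flag). Macro is the
common default for imbalanced medical data and matches the per-class
formulas; the averaging scheme is stated because a single reported number
is otherwise ambiguous. Zero-denominator classes contribute 0 with a
warning — explicit and conservative.

`run_ablation()` reruns pretraining plus linear probing for five
configurations — baseline (augmentation, projection and prediction all
removed), each component alone, and the full method — under one shared
seed, mirroring the component-ablation protocol. When a head is ablated
the next vector in the chain feeds the loss directly (the prediction MLP
is then sized to the encoder width).

## Desk-scale problem sizes

The package's own acceptance experiments run on one CPU in minutes, with
sizes chosen as the smallest at which the studied effects are visible and
stable: the learning experiment uses the tinycnn backbone (feature width
64, projection width 128, prediction bottleneck 32 — preserving the 4:1
bottleneck ratio of the reference architecture) on the default synthetic
dataset (4 classes × 50 images, 64 px) for 30 epochs at batch size 32;
the ablation study uses a narrower model (32/64/16) for 4 epochs per
configuration across 5 seeds. Reference-scale settings (ResNet-50,
8192-wide projection, 200 epochs) remain the defaults of
`model_config()`/`train_config()` and are exercised structurally (shape
checks) rather than by full training.

## Known limitations

* Training is single-threaded base R; it is meant for desk-scale
  experiments and correctness, not for pretraining at dataset scale.
* No momentum/EMA target encoder, no negative pairs, no memory bank, no
  multi-crop: these are deliberately out of scope, as the method's point
  is that none of them is needed.
* Checkpoints are R serialisations (versioned container); they are not
  interoperable with other frameworks.
* The reported minimum of the loss is attained only at exactly collinear
  inputs; with the $10^{-12}$ norm epsilon the computed value at the
  minimizer is $-1$ to within $10^{-11}$.
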