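# triview

Self-supervised pretraining of image encoders from **unlabelled** images,
for settings — typical of medical image analysis — where unlabelled data is
plentiful and annotation is expensive. The package pretrains an encoder by
aligning three augmented views of each image, then evaluates the learned
representation by linear probing or fine-tuning with only a fraction of the
labels.

## The method

Each image `x` passes three times through a stochastic augmentation module
(random resized crop, colour jitter, greyscale, Gaussian blur, flips),
giving views `x1, x2, x3`. One shared parameter set — encoder `E`
(ResNet-50 by default), projection MLP `P`, prediction MLP `H` — maps every
view to a projection `v_i = P(E(x_i))` and a prediction
`z_i = H(P(E(x_i)))`. Training minimizes the six-term pairwise negative
cosine similarity

    L = (1/3) [ ½N(z1,v2) + ½N(z2,v1) + ½N(z1,v3)
              + ½N(z3,v1) + ½N(z2,v3) + ½N(z3,v2) ],

with `N(z,v) = −(z/‖z‖)·(v/‖v‖)`, a **stop-gradient on every projection
target** `v_j`, SGD (momentum 0.9, weight decay 5e-4) and a cosine-decayed
learning rate starting at 0.05. The minimum value of the loss is −1. No
negative pairs, no momentum encoder, no large batches: the stop-gradient
plus the prediction bottleneck prevent representational collapse, which the
package monitors with a per-batch collapse metric (mean per-dimension
standard deviation of the l2-normalized projections).

Everything is implemented in base R with explicit forward/backward passes
(gradients verified against finite differences in the test suite), a
deterministic splittable RNG, and a built-in synthetic labelled-image
generator so the entire pipeline is testable on one CPU with no downloads.

## Worked example

```r
library(triview)

# a deterministic 4-class synthetic dataset (80 images, 32 px)
ds <- generate_dataset(synthetic_spec(n_per_class = 20, image_size = 32,
                                      seed = 1))

cfg <- train_config(
  image_size = 32, epochs = 8, batch_size = 16,
  model = model_config("tinycnn", feature_dim = 16, proj_dim = 32,
                       pred_hidden_dim = 8),
  seed = 1
)
fit <- triview(ds, cfg)
fit
#> Triple-view self-supervised pretraining fit
#>   backbone: tinycnn (feature 16, proj 32, pred hidden 8)
#>   80 images, 8 epochs, batch 16, base lr 0.05
#>   loss: -0.0702 (first epoch) -> -0.1523 (final epoch)
#>   collapse metric (final epoch): 0.1744

# linear evaluation with 25% of the training labels
report <- linear_probe(fit, ds, split_spec(labelled_ratio = 0.25, seed = 1))
report
#> Evaluation report (n = 16, macro-averaged)
#>   accuracy 0.9375  precision 0.9500  recall 0.9375  F1 0.9365
```

The pretraining loss falls (alignment of the three views improves), the
collapse metric stays an order of magnitude above zero (no constant
solution), and a linear classifier on the frozen encoder separates the four
classes from 16 labelled images at 94% test accuracy. `plot(fit)` draws the
loss and collapse traces; `predict(fit, images, type = "features")`
extracts encoder features; `fine_tune()` trains encoder and head end to
end; `run_ablation()` reruns pretraining with the augmentation module,
projection MLP and prediction MLP switched on/off in the five standard
configurations.

Real class-per-subdirectory PNG/JPEG datasets are read with
`read_image_folder()`; `model_config()` defaults to the reference
architecture (ResNet-50 encoder, 8192-wide projection, 2048-wide
bottleneck).

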