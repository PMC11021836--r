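Package: triview
Title: Triple-View Self-Supervised Representation Learning for Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised pretraining of image encoders from unlabelled
    data using three stochastically augmented views per image, a shared
    encoder with projection and prediction multilayer perceptrons, and a
    six-term negative cosine similarity loss with stop-gradient on the
    projection targets. Includes the full augmentation pipeline (random
    resized crop, colour jitter, greyscale, Gaussian blur, flips), SGD
    pretraining with a cosine-decayed learning rate, representation-collapse
    diagnostics, a deterministic synthetic labelled-image generator for
    testing, and downstream evaluation by linear probing and fine-tuning
    under partial label availability with confusion-matrix based metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
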