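Package: gazedistill
Title: Gaze-Based Autism Classification with Training-Data Attribution and
    Influence-Guided Dataset Distillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies viewers as autistic (ASD) or typically developing (TD)
    from eye-tracking scanpaths recorded while they look at natural images.
    Provides readers for the aggregated scanpath text dialect used by gaze
    free-viewing corpora (per-participant fixation index, x, y, duration),
    duration-proportional scanpath augmentation with spatial jitter, fixation-map
    rasterization, and a three-branch neural classifier (two convolutional
    branches over the stimulus image and the fixation map, one LSTM branch over
    the fixation sequence) trained with Adam on binary cross-entropy, with
    per-epoch parameter checkpoints. Checkpoint replay implements TracIn-style
    training-data attribution: self-influence scores for outlier and label-noise
    screening, pairwise train-by-test influence with proponent/opponent ranking,
    and an influence-guided dataset distillation protocol that retrains on the
    lowest-self-influence subset and compares it against matched random subsets
    and the full training set. A synthetic gaze generator with a planted
    social-attention effect makes every stage runnable and testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
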