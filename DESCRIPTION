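Package: gazecam
Title: Gaze-Supervised Attention Networks for Lesion Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training image classifiers whose internal class-activation
    attention is supervised by human eye-gaze. Converts eye-tracker fixation logs
    into Gaussian gaze-attention maps using a viewing-geometry error model, trains
    a convolutional classifier under a joint cross-entropy plus
    attention-consistency (mean squared error) objective, and evaluates with a
    one-vs-rest multiclass metric suite (accuracy, precision, recall, F1, Matthews
    correlation, Cohen's kappa, rank-based AUC) together with an
    attention-to-lesion alignment score. A synthetic phantom-lesion and simulated
    scanpath generator makes the whole pipeline runnable and testable without an
    eye tracker or clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
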