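Package: paindecode
Title: Decoding Perceived Pain Intensity from Pre- and Post-Stimulus Brain Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-trial decoding of perceived pain intensity from neural
    features recorded before and after a nociceptive stimulus. Epoched EEG is
    turned into time-frequency power features by short-time Fourier transform,
    and BOLD fMRI into onset-scan and peak-scan voxel features; features and
    visual-analogue-scale ratings are normalized within stimulus-energy
    groups. Pain-related patterns are discovered by per-subject partial
    least-squares regression (NIPALS) followed by point-wise one-sample t-tests
    with cluster-based sign-flip permutation inference, and perceived pain is
    predicted per trial with leave-one-out cross-validated linear support
    vector classification and regression. A synthetic-cohort generator plants
    pre- and post-stimulus effects with known ground truth so that every stage
    of the pipeline can be validated without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
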