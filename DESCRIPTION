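Package: ktfmri
Title: Compressed-Sensing Reconstruction and Evaluation for Non-EPI fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrospective compressed-sensing study tools for dynamic
    (2D+time) non-EPI functional MRI. Implements Cartesian k-t undersampling
    mask generators (uniform, Gaussian, Gaussian/uniform mixtures with and
    without guaranteed centre-line sampling, a contiguous centre-block
    control, and an eddy-current-suppressing pairwise variant), the k-t
    FOCUSS iteratively reweighted least-squares reconstruction with temporal
    Fourier and Karhunen-Loeve sparsifying transforms solved by conjugate
    gradients, activation statistics (Welch t-score maps with cluster-extent
    rejection, ROC/AUC against a fully sampled reference, frame-wise and
    average normalized mean squared error), and a synthetic phase-cycled
    balanced SSFP / spoiled gradient-echo phantom generator with a block
    stimulation paradigm so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
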