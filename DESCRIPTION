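Package: devrsa
Title: Representational Similarity Analysis for Developmental fMRI Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing representational geometry in
    developmental functional MRI studies. Implements a first-level general
    linear model with framewise-displacement spike censoring and
    dispersion-based voxel filtering, cross-subject representational
    similarity matrices (RSMs) with split-half noise ceilings corrected by
    the Spearman-Brown prophecy formula, bootstrap inference over
    subject/run pairs with motion-matched importance reweighting,
    perceptual and categorical model RSMs, covariance-trace variance
    partitioning into group, individual and session components, layerwise
    alignment to convolutional network activations, and hierarchically
    aligned SMACOF multidimensional-scaling embeddings. A synthetic cohort
    generator with known ground-truth mixtures provides an end-to-end test
    bed with recoverable parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
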