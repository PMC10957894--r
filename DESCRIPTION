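Package: natsemsoc
Title: Semantic and Social Content Analysis for Naturalistic Movie fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for analysing semantic and social content in
    naturalistic movie-viewing fMRI. Builds word-level psycholinguistic
    predictors (chained-equation imputation, varimax-rotated principal
    component factor scores, embedding-based socialness extrapolation) and
    event-level predictors (rated movie events with short-event merging and
    inter-rater reliability), turns them into event-bounded sliding-window
    time courses and HRF-convolved parametric modulators, fits voxelwise
    subject-level GLMs and group mixed-effects maps with Monte-Carlo
    cluster-extent familywise error correction, and quantifies overlap
    between thresholded statistical maps (Dice coefficient, normalized
    statistical-overlap maps, conjunctions, network comparisons). Includes
    a calibrated synthetic-data generator so the full pipeline can be
    exercised and validated without access to the original dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    yaml,
    optparse
Config/testthat/edition: 3
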