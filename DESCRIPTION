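Package: limbclass
Title: Data-Driven Classification of Limb Status from Biomechanical Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven framework for classifying time-normalized
    biomechanical waveforms (101 samples per movement cycle) into three limb
    classes: the ACL-operated limb, the contralateral non-operated limb, and
    healthy-control limbs. Implements robust-phase feature engineering via a
    memory matrix accumulated over resampled subject subsets, a uniform panel
    of supervised learning techniques evaluated with subject-level stratified
    shuffle-split cross-validation, forward wrapper feature selection with
    collinearity pruning and an elbow-based minimal feature model, and
    multi-level (limb, group, subject) confusion and sensitivity accounting.
    Ships a synthetic waveform generator with planted, localized class
    effects so the entire pipeline is testable without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    MASS,
    class,
    rpart,
    nnet,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
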