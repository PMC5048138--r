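Package: phosT
Title: Phosphothreonine Site Prediction from Sequence, Structure and
    Physicochemical Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts phosphothreonine sites in proteins from 31-residue
    threonine-centered windows. Implements position-conservation profiling,
    positive/negative position weight matrix (PWM) difference scoring,
    encoding of secondary structure, accessibility and nine amino-acid
    physicochemical properties at per-group optimal window sizes, minimal
    redundancy maximal relevance (mRMR) feature ranking with incremental
    feature selection, and RBF-kernel support vector machine evaluation by
    jackknife (leave-one-out) ROC analysis. Includes a synthetic data
    generator that emulates the compositional, structural and accessibility
    signatures of phosphothreonine contexts so the full pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    readr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
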