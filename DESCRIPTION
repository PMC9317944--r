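Package: facesym
Title: Landmark-Based Facial Symmetry Features for Facial Palsy Screening
Version: 0.1.0
Authors@R:
    person("facesym", "developers", email = "facesym@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify facial asymmetry from 2-D facial landmarks and
    to grade unilateral facial palsy as a classification problem. Implements
    the 51-point renumbering of the standard 68-point facial model, head-tilt
    correction by a closed-form two-point similarity transform, 29 geometric
    symmetry features built from 28 named inter-landmark distances and two
    eyebrow-height averages, and regional feature subsets for the eyes and
    mouth. Ships a synthetic-face generator with parameterized unilateral
    droop so the full pipeline (feature extraction, rotation augmentation,
    repeated stratified k-fold cross-validation with MLP, SVM, KNN and
    multinomial logistic classifiers, confusion-matrix metrics, ARFF export)
    is testable without access to clinical image databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
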