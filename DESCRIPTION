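Package: petmci
Title: Longitudinal FDG-PET Features for Predicting MCI-to-AD Conversion
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification framework for distinguishing progressive from
    stable mild cognitive impairment (MCI) using longitudinal FDG-PET scans
    and cognitive scores. Implements two-step reference-cluster (Yakushev)
    intensity normalization, atlas-based regional feature extraction with
    age/gender confound removal, longitudinal dynamic difference and
    change-rate features, F-score feature ranking, and leave-one-out RBF-SVM
    evaluation with ROC/AUC reporting. Includes a synthetic-cohort generator
    with planted group effects so every stage of the pipeline can be
    exercised and validated without access-controlled clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
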