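Package: neurofuse
Title: Multimodal MRI Fusion Classification and Personalized Diagnostic
    Maps for Autism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-stage pipeline for personalized autism diagnosis from
    region-level structural MRI morphometry and resting-state functional
    MRI time courses on the 68-region Desikan-Killiany parcellation.
    Builds per-subject antisymmetric pairwise-difference (delta) tensors
    from eight morphometric features and Pearson functional-connectivity
    matrices, trains one k-nearest-neighbour classifier per pairwise
    feature to rank features by cross-validated accuracy, selects
    ranked-feature prefixes incrementally with a grid-searched random
    forest, fuses the optimal prefixes of both modalities into a global
    classifier, derives per-subject per-region autism-probability maps,
    and screens every pairwise feature for correlation with ADOS symptom
    severity. Includes a synthetic-cohort generator with planted
    class-discriminative and severity-correlated effects so the whole
    pipeline is testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    ranger,
    e1071,
    nnet,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    RNifti,
    optparse,
    yaml
Config/testthat/edition: 3
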