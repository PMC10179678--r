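Package: deldyn
Title: Intrinsic-Dynamics Features and Positive-Unlabeled Classification
    of Multi-Residue Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a deletion of multiple contiguous amino acids
    is tolerated by a protein fold. Builds Gaussian and anisotropic elastic
    network models on the C-alpha trace of a wild-type structure, derives six
    per-residue intrinsic-dynamics profiles (mean-square fluctuations in
    global and local modes, perturbation-response effectiveness and
    sensitivity, mechanical stiffness, and essential-site scanning scores),
    aggregates them over a deletion segment into a 37-component feature
    vector, and classifies segments with a two-stage positive-unlabeled
    random-forest scheme (Elkan-Noto weighting) evaluated by recall and
    fall-out under stratified cross-validation. Includes generators for
    synthetic structures with known network spectra and for
    positive-unlabeled feature tables with known labeling frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
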