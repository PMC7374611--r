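Package: semenc
Title: Semantic Encoding Models for Neural Responses to Film
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives low-dimensional semantic components from per-frame concept
    labels of a film via word embeddings and principal component analysis, fits
    confound-controlled ridge encoding models to electrocorticographic
    high-frequency-band responses across stimulus-response time shifts, compares
    the semantic model against low-level pixel and Gabor-energy controls and a
    binary-label model, groups encoding weights into functional networks with
    affinity-propagation clustering and a permutation null, and smooths
    electrode values onto a spherical surface grid with a Gaussian-process
    interpolator. A synthetic-data generator with planted ground truth (labels,
    embeddings, confounds, lagged responses) makes every stage testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
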