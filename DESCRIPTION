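Package: tadscout
Title: Fragment-Resolution Hi-C Contact Matrices and Statistical TAD Boundary Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds restriction-fragment-resolution Hi-C contact matrices from
    filtered read pairs, applies iterative correction (ICE) and per-distance
    z-score normalization, and calls topologically associating domain (TAD)
    boundaries as statistically significant local minima of a multi-scale
    TAD-separation score. Downstream utilities classify TADs by chromatin-mark
    signal, validate boundaries against insulator peaks, compute Pol-II pausing
    indices, score motif binding affinity with the TRAP biophysical model,
    test boundary-versus-background motif enrichment, and train a sparse
    logistic classifier to predict boundaries from sequence features. A
    simulation module generates genomes, read pairs, contact matrices with
    planted domains, chromatin tracks and motif-planted promoter sets so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    Matrix,
    Biostrings,
    glmnet,
    generics,
    ggplot2,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
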