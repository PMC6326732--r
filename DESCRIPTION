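Package: cyclicity
Title: Cyclicity Analysis of Multichannel Time Courses via Lead Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Leader-follower structure in cyclic but aperiodic multichannel
    signals, extracted through the antisymmetric matrix of pairwise signed
    areas (the lead matrix, a second-order iterated path integral) and its
    spectral decomposition. Includes a synthetic resting-state cohort
    generator, cross-session subject fingerprinting by 1-nearest-neighbour
    cosine matching, Wilks' lambda feature selection with Monte Carlo
    stability, group classification protocols (SVM, discriminant analysis,
    PLS-DA) with Monte Carlo half-split averaging, and leader-follower
    graph construction with layered layout.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
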