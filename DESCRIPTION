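Package: raseffector
Title: Interface Contact Matrices and Binding Affinities for RAS-Effector Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the interface between RAS-family GTPases and
    their effector RB/RA domains. Builds aggregated residue-level interaction
    matrices from multiple complex structures via alignment-synchronized
    contact mapping at a heavy-atom distance cutoff, decomposes contacts into
    main-chain/side-chain categories, detects dense binding-hotspot regions,
    and estimates equilibrium dissociation constants from fluorescence
    polarization titrations with the exact (tight-binding) quadratic isotherm.
    Includes synthetic generators for toy complexes, alignments, planted-block
    matrices and simulated titrations so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
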