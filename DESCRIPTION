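Package: posestab
Title: Pose-Consistency Analysis of 3D Molecular Descriptors over Docking Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how stable 3D molecular descriptors (3D-MoRSE, CPSA,
    gravitational indexes, moments of inertia, geometric shape indexes) are
    across an ensemble of docking poses of the same compound. Reads
    multi-conformer SDF files, computes per-conformer descriptor vectors
    (including Shrake-Rupley solvent-accessible surface areas and
    Gasteiger-Marsili partial charges), superposes poses by the Kabsch
    algorithm to measure atom-position fluctuation, summarises per-compound
    descriptor variability over the top-k scored poses, compares active and
    inactive compound populations, correlates variability with rotatable-bond
    counts, and embeds per-compound variability vectors into 2D for
    visualisation. Ships a seeded synthetic pose-ensemble generator so the
    whole pipeline runs without commercial docking software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    igraph,
    stats,
    utils,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
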