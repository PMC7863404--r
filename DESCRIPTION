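Package: otoquant
Title: Quantitative Analysis of Cochlear Hair-Cell Imaging, Auditory
    Physiology, and Auditory Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end quantification toolkit for inner-ear
    gene-therapy studies in the mouse. Segments hair-cell nuclei in
    multi-channel 3D confocal stacks (Otsu thresholding, Euclidean
    distance transform, marker-based 3D watershed), classifies inner
    versus outer hair-cell rows, measures nuclear position along an arc
    fitted through the apical surface, nucleus center, and basal end of
    each cell, counts surviving hair cells in 100 micrometre cochleogram
    bins, and converts between stimulus frequency and cochlear place via
    a mouse place-frequency map. Extracts auditory brainstem response
    (ABR) thresholds, P1-N1 amplitudes and P1 latencies, and
    distortion-product otoacoustic emission (DPOAE) 2f1-f2 amplitudes
    and noise floors. Scores freezing and activity in cued fear
    conditioning and rotation, distance, and center-time in open-field
    tests. Includes a synthetic-data generator with known ground truth
    for every modality, the study-level statistical layer (Pearson
    correlation, Holm-Sidak adjustment, balanced two-way ANOVA, paired
    contrasts), and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
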