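Package: vertemorph
Title: Automated Quantitative Vertebral Morphometry from Lateral Spine Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage quantitative morphometry (QM) pipeline for thoracolumbar
    vertebral bodies in lateral radiographs. Stage one detects vertebral bodies
    as instance masks, reduces each to its centre of gravity, and rejects false
    detections by fitting a low-degree polynomial spinal curve with RANSAC.
    Stage two places the six Genant-style landmarks (anterior, central and
    posterior upper/lower points) on fixed-size vertebral crops, from which
    anterior (A), central (C) and posterior (P) heights, the height ratios
    C/A, C/P and A/P, collapse percent and QM status bins are computed. An
    observer-agreement evaluation suite implements detection sensitivity and
    precision, dimension-normalised landmark errors, normality-gated
    Pearson/Spearman correlation, and Bland-Altman limits-of-agreement analysis
    with QM-status subgroups and proportional-bias regression. A synthetic
    spine-phantom generator with exact ground truth (masks, landmarks, deformity
    severities, confuser structures) makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
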