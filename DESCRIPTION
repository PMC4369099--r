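Package: lincfish
Title: Single-Molecule RNA FISH Quantification and Localization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies single-molecule RNA fluorescence in situ hybridization
    (smFISH) experiments from 3-D image stacks: Laplacian-of-Gaussian spot
    enhancement, plateau-based intensity thresholding, 2-D Gaussian amplitude
    fitting, autofluorescence exclusion, two-stage cross-channel
    co-localization with rigid registration, even/odd two-color probe-set
    validation (Mann-Whitney criterion), nuclear/cytoplasmic localization
    classification (classes I-V), and single-cell abundance and variability
    statistics (Poisson reference, mean-median regression, jackpot-cell power
    bounds, marker correlations). Includes a seeded synthetic-experiment
    generator producing image stacks, segmentation masks and molecule-level
    ground truth so every stage can be tested without microscopy data.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
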