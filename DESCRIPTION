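Package: edmerge
Title: Multi-Crystal Electron Diffraction Data Reduction by Hierarchical
    Cluster Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data reduction for serial continuous-rotation electron
    diffraction (cRED/microED) experiments that collect many partial
    datasets from sub-micrometre crystals. Implements the two-stage
    hierarchical cluster analysis used for multi-crystal phase analysis
    and merging: stage one clusters datasets on unit-cell parameters or
    cell volume (with histogram-based cell averaging and lattice-type
    voting), stage two clusters on pairwise correlation coefficients of
    common reflection intensities via the distance sqrt(1 - CC^2),
    followed by per-cluster scaling, merging and crystallographic quality
    statistics (completeness, R_meas, CC_1/2, I/sigma). Includes Laue
    group operator sets with asymmetric-unit reduction and unique
    reflection enumeration, readers/writers for SHELX HKL4 files and
    XDS-style log dialects, image algorithms for defocused-beam crystal
    tracking and isolated-crystal selection, and a synthetic multi-phase
    generator so the whole pipeline is testable without a microscope.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
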