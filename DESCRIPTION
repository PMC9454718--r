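Package: camquant
Title: Quantification of Chorioallantoic Membrane Vasculature and
    Method-Comparison Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantitative assessment of angiogenesis in
    chorioallantoic membrane (CAM) style microscopy images. Generates
    reproducible synthetic vascular networks with exact ground truth,
    segments vessels with a classical multiscale tubularity pipeline,
    computes skeleton- and area-based morphometry (branching points, total
    length, mean thickness, vessel count, density, lacunarity), emulates a
    manual ImageJ-style counting protocol and an ImageScope-style positive
    pixel count with exclusion regions, and compares any two measurement
    methods with Bland-Altman limits of agreement and paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
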