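Package: epmorph
Title: Morphometry and Classification of Lumbar Vertebral Endplate Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative morphometry of lumbar vertebral endplate
    surfaces from triangulated 3D models. Reads and writes STL surface meshes,
    extracts mid-sagittal and mid-coronal cross-section profiles, measures the
    standard concavity parameters (chord diameter, maximum concavity depth,
    margin-to-apex lengths, asymmetry ratio, plateau fraction), classifies
    endplates into four morphological types (uniformly concave, asymmetric
    concave, flat-bottomed concave, flat), and reproduces the cohort-level
    statistical battery used in endplate morphology studies: pooled two-sample
    t-tests with Cohen's d from summary statistics, chi-square with Cramer's V,
    the Freeman-Halton exact test for r x c contingency tables, and ICC(A,1)
    inter-rater reliability. Includes a parametric synthetic endplate generator
    for validation and a reproducible cohort reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
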