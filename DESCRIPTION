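Package: isointense
Title: Intensity-Matched Comparison of Pain and Touch fMRI Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing event-related BOLD responses to painful and
    tactile stimuli whose perceived intensity has been matched on a
    trial-by-trial basis. Implements trial-level perceived-intensity matching,
    first-level general linear models (a five-condition event model and a
    parametric perceived-intensity model) with canonical double-gamma
    hemodynamic regressors, second-level nonparametric sign-flip permutation
    inference with voxel-level and cluster-extent family-wise error control,
    model-free region-wise BOLD time-course extraction with rating-period
    template removal and area-under-the-curve statistics, and a median-split
    intensity-mismatch comparison. A synthetic multi-subject cohort generator
    reproduces the study design (two sessions of twenty-four 25-s trials,
    TR = 0.8 s) so that every stage is testable end to end without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
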