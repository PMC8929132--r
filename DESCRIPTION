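Package: sorghumTPE
Title: Water and Heat Stress Envirotyping for Sorghum Target Populations of
    Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Characterizes the target population of environments (TPE) for
    grain sorghum from daily weather. A simplified daily crop model tracks
    phenology in thermal time, a layered soil water bucket, and two seasonal
    stress indices: relative transpiration (RT, the root water supply to
    canopy demand ratio) and a grain temperature heat index (GT, maximum
    temperature above 32 C inside the seed-set window). Seasonal index
    trajectories are binned on a 100 degree-day grid, clustered with k-means
    into water (WSP) and heat (HSP) stress patterns, and regrouped into four
    yield-relevant environment categories (ECG). Companion tools classify
    independent site-years by nearest centroid, estimate random-effect
    variance components of trial yields, complete unbalanced genotype by
    environment tables by low-rank singular-value imputation, and draw the
    genotype by ECG biplot. A stochastic weather generator and a trial-table
    simulator with known variance structure make the whole pipeline testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    withr,
    cluster,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
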