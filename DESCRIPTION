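Package: hauloutr
Title: Plot-Sampling Abundance Estimation for Pinniped Haulouts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automated estimation of the number of animals aggregated
    on shore from georeferenced survey polygons. Builds a square sampling
    grid over digitized haulout outlines, clips the cells to the outline,
    randomly selects a fraction of cells as model polygons, reduces
    multi-observer counts to per-polygon summaries, and produces abundance
    estimates by three routes: direct density extrapolation with a
    simulation confidence interval, a linear regression of counts on
    polygon area, and a pooled negative-binomial GLM with a terrain
    covariate and a log-area offset with delta-method intervals. Includes a
    synthetic-haulout generator with known ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
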