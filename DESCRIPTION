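Package: microinjectr
Title: Image-Guided Single-Cell Microinjection: Calibration, Planning,
    Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of an image-guided robotic microinjection
    workflow for organotypic brain slices. Estimates the linear transform
    between three-axis micromanipulator displacements and microscope camera
    pixels, plans constant-pressure injection trajectories along an annotated
    tissue edge, executes plans against simulated hardware (manipulator,
    pressure chain, camera) with a configurable stochastic outcome model,
    and quantifies the downstream biology: distance-from-ventricle binning,
    zone and marker distributions, gap-junction dye-coupling clusters, and
    exact Wilcoxon rank-sum statistics computed by full enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
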