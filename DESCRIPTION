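Package: lineFRAP
Title: Line Fluorescence Recovery After Photobleaching Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures lateral diffusion in supported lipid bilayers and other
    membranes from line fluorescence recovery after photobleaching (line FRAP)
    experiments.  Implements the closed-form recovery model for a Gaussian line
    bleach observed through a Gaussian imaging profile, multi-component fits
    with a mobile fraction, an empirical double-exponential backend with
    rate-to-diffusion conversion, extraction of normalized recovery curves from
    confocal time-lapse stacks, a Brownian-dynamics generator of ground-truthed
    synthetic line-FRAP datasets (two diffusing species, immobile fraction,
    impermeable gel-domain obstacles, Poisson detection noise), and batch
    aggregation across experimental conditions with a descriptive
    temperature-trend assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
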