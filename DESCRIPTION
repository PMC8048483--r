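Package: canopyfsp
Title: Functional-Structural Simulation of Arabidopsis Canopy Shade Avoidance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A functional-structural plant (FSP) simulator of Arabidopsis
    rosette canopies. Rosettes are collections of petiole+lamina leaf organs
    growing in 3D; a Monte-Carlo two-band (red, far-red) plus PAR radiation
    model drives photosynthesis, carbon allocation and the shade-avoidance
    responses (hyponasty and petiole elongation) triggered by leaf touching
    or a low red:far-red ratio at the lamina tip. Scenario machinery
    simulates monoculture stands invaded by competitor plants of weak or
    strong shade-avoidance phenotypes, and reports soil-level light
    penetration and central-plant biomass under different hyponasty rates.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
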