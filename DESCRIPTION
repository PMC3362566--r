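Package: npzdcolumn
Title: Nitrogen-Based NPZD Plankton Ecosystem Model in Box and Vertical-Column Configurations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of a four-compartment nitrogen-based
    nutrient-phytoplankton-zooplankton-detritus (NPZD) ecosystem with a dynamic
    Geider-type chlorophyll-to-carbon ratio, in zero-dimensional box and
    one-dimensional vertical-column configurations. Includes light attenuation by
    water and chlorophyll, implicit vertical diffusion, upwind tracer sinking and
    prescribed upwelling, idealized upwelling-event forcing scenarios, river
    nutrient source tables, and model-skill statistics (model bias, zero-phase
    low-pass filtering, disc averaging of gridded fields).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    geosphere,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
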