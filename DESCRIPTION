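Package: dgdose
Title: Distorted Grid Particokinetics for In Vitro Nanomaterial Dosimetry
Version: 0.1.0
Authors@R:
    person("dgdose", "maintainers", email = "dgdose@example.org", role = c("aut", "cre"))
Description: One-dimensional compartmental sedimentation-diffusion transport
    model ("Distorted Grid") for suspensions of engineered-nanomaterial
    agglomerates in a cell-culture well column.  Supports polydisperse size
    distributions, Stokes-Einstein diffusion and gravitational settling with
    Cunningham slip and dynamic shape-factor friction corrections, a Langmuir
    isotherm cell-binding bottom boundary, dissolution scenarios, and dose
    metrics expressed as mass, particle number and nanomaterial surface area.
    Includes closed-form equilibrium and Brownian-dynamics reference models
    for verification, material presets, a JSON configuration loader and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
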