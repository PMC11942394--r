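Package: gelfront
Title: Reaction-Diffusion Simulation and Front Tracking of Barium-Alginate Gelation
Version: 0.1.0
Authors@R: person("gelfront", "maintainers", email = "gelfront@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator for the gelation of ultra-high-viscosity
    alginate by inward diffusion of barium ions. Integrates four coupled
    reaction-diffusion equations (free polymer, free barium, cross-linked
    polymer, binding occupancy) on radially symmetric slab, disc and sphere
    domains with cross-link-hindered diffusivities, extracts the travelling
    gelation front and its two-phase velocities, generates synthetic
    phase-contrast-like time-lapse image stacks with an image-based front
    tracker mirroring the experimental measurement, and calibrates model
    parameters against observed front trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
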