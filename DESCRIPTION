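Package: stripesim
Title: Multiscale Simulation of Stripe Formation in Engineered E. coli Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid agent-based and mean-field PDE simulators for sequential
    stripe formation in colonies of engineered Escherichia coli in which a
    quorum-sensing module suppresses motility through the phosphatase CheZ.
    The package implements the intracellular chemotaxis signaling pathway
    (receptor activity, phospho-protein quasi-steady states, methylation and
    CheZ dynamics), a flagellar-voting model mapping CheYp to whole-cell
    run/tumble switching rates, a velocity-jump agent-based simulator coupled
    to reaction-diffusion fields for the quorum signal AHL and nutrient, the
    derived mean-field density PDE with an internal CheZ state variable (1D
    Cartesian and 2D radially symmetric), a reduced switch-diffusivity model,
    and pattern metrics (front speed, wavelength, height ratio, density
    ratio, stripe counts).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
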