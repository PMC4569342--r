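Package: SyxDynamics
Title: Particle-Based Simulation and STED Image Analysis of Syntaxin-1A
    Membrane Nanoclusters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study the self-assembly and exchange dynamics of
    Syntaxin-1A nanoclusters on the presynaptic membrane. Provides an
    overdamped Brownian-dynamics engine for a two-particle (anchor/head)
    dimer model of Syntaxin-1A with piecewise-harmonic membrane, repulsion
    and clustering potentials; cluster identification and kinetics
    (size distributions, cluster diffusion, dissociation rates, residence
    times); simulated assays (FRAP, membrane exploration, seeded
    aggregation at a docking site, docking/priming candidate census); a
    STED image-analysis pipeline (windowed local-maximum spot detection,
    FWHM sizing, Bruchpilot-ring active-zone definition, cluster
    classification and group comparison); and synthetic-data generators
    for both images and trajectories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    yaml,
    tiff,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
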