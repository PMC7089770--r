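Package: rodtrack
Title: Single-Molecule Tracking and Binding Kinetics of Bacterial
    Cell-Wall Synthesis Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of sparse single-particle tracking (sptPALM) data for
    membrane-bound bacterial enzymes such as the transpeptidase PBP2.
    Decomposes trajectory ensembles into bound and diffusive populations by
    jump-length-distribution mixture fitting and by the distribution of
    single-track effective diffusion constants; classifies bound-molecule
    trajectories into immobile and persistently moving states with a
    simulation-calibrated velocity threshold and estimates state-transition
    rates; infers binding and unbinding kinetics from photobleaching-corrected
    track-lifetime distributions, bound-molecule FRAP recovery and detailed
    balance; simulates Brownian-dynamics target search with optional
    facilitated one-dimensional diffusion along filaments; and correlates
    cell-boundary fluorescence with contour curvature, including corrections
    for cell bending. Seeded generators for all synthetic inputs are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite
Config/testthat/edition: 3
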