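Package: optospread
Title: Spatial and Temporal Spread of Optogenetic Cortical Inactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for characterizing how far and how fast
    optogenetic silencing spreads in cortex. Recovers the three-dimensional
    profile of light intensity in tissue from photobleaching of nuclear
    fluorophores (exponential dose model, delta-F/F0 inversion), classifies
    extracellular units into fast-spiking and putative pyramidal classes by
    trough-to-peak spike width, and computes inactivation statistics:
    peristimulus time histograms, relative spike rates (unit and population
    conventions), spatial suppression profiles with bootstrap uncertainty and
    half-max radius, onset and earliest-change latencies, rebound indices, and
    a paradoxical-effect scan for inhibition-stabilized network signatures.
    Includes synthetic-data generators (bleached-nuclei volumes, inhomogeneous
    Poisson spike datasets) and a rate-based excitatory-inhibitory network
    simulator with optional spatial coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    tiff,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
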