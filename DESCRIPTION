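Package: microptv
Title: PIV-Assisted Particle Tracking Velocimetry Around a Pinned Micro-Droplet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for micro-scale flow and biofilm
    measurements around a pinned oil micro-droplet in a microchannel, using
    suspended bacterial cells as flow tracers. Provides window cross-correlation
    micro-PIV, PIV-assisted particle tracking velocimetry, scattered-to-grid
    interpolation by local least-squares Taylor expansion, nondimensional
    viscous-stress and streamwise momentum-budget maps with inferred pressure
    gradients, and droplet-aggregate morphometrics (film thickness versus angle,
    streamer tail extent). A synthetic-scene generator renders tracer image
    sequences over analytic ground-truth flows so the full pipeline is testable
    without experimental imagery.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    EBImage,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
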