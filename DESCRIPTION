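Package: flygait
Title: Gait Analysis of Walking Drosophila from Frustrated Total Internal
    Reflection Footprint Videos
Version: 0.1.0
Authors@R:
    person("flygait", "developers", email = "flygait@example.org",
           role = c("aut", "cre"))
Description: Tracks the body and tarsal contact footprints of a freely
    walking fly in high-speed image sequences acquired with frustrated
    total internal reflection (fTIR) imaging, and computes a complete
    suite of temporal, spatial, gait-classification and inter-leg
    coordination parameters: step period, stance and swing durations,
    step length, swing speed, metachronal lag, inter-leg phases with
    circular statistics, stance traces with anterior and posterior
    extreme positions, stance linearity, footprint clustering and
    alignment, per-frame leg-combination coding, tripod/tetrapod
    classification, gait maps and gait indexes.  A parametric synthetic
    walking-fly renderer with ground truth makes the entire pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
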