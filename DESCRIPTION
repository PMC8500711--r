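Package: riskforage
Title: Amygdala-Hippocampus Spike-Train Analysis for Risky Foraging Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous basal amygdala (BA) and
    dorsal hippocampus (dHPC) single-unit recordings from rats foraging
    under predatory threat. Provides place-field rate maps with Skaggs
    spatial information and Fisher-Z map-stability metrics, peri-event
    time histogram (PETH) classification of amygdala units, epoch-restricted
    shift-predictor-corrected cross-correlograms with peak-Z significance
    and lead/lag directionality, theta-band (6-10 Hz) spike-train spectra,
    and linkage statistics relating fear-cell synchrony to place-field
    remapping. Includes a synthetic foraging-session simulator (trajectory,
    events, coupled inhomogeneous-Poisson spike trains) with ground-truth
    labels so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    nortest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
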