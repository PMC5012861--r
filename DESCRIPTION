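Package: barmkit
Title: Simulation and Analysis of Blink-Associated Resetting Eye Movements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying blink-associated resetting movements (BARMs)
    of the eye in 3D video-oculography and scleral search-coil recordings.
    Provides a calibrated generator of synthetic experimental blocks
    (torsional optokinetic stimulation alternating with fixation in
    darkness, including blinks, stimulus blanking, and a two-component
    coil-domain blink movement), blink detection with temporal safety
    margins, slow/fast-phase segmentation of torsional nystagmus,
    measurement of blink- and fast-phase-associated torsional shifts,
    two-component decomposition of coil traces, main-sequence analysis,
    and the statistical layer used to dissociate BARMs from optokinetic
    fast phases (phase-wise regressions, pooled-versus-split cluster
    diagnostics, bootstrap correlation inference, and 2D regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
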