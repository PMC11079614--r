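Package: fstflux
Title: Filter-Space Technique Energy Flux Analysis for Quasi-2D Flows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring the cross-scale spectral energy flux in
    time-resolved two-dimensional velocity fields with the filter-space
    technique (a posteriori coarse-graining). Computes the turbulent
    stress tensor and its Leonard/cross/subgrid-Reynolds and Germano
    decompositions, the filtered rate-of-strain tensor, eigenframe
    alignment angles, and the tensor-geometry form of the flux. Includes
    a synthetic-data generator (uniform shear, angled swimmer-like jets,
    intermittent schedules, particle-tracking-velocimetry emulation and
    Eulerian reconstruction), a minimal doubly periodic pseudo-spectral
    quasi-2D solver with linear friction, and shear-modification
    diagnostics, so that the full analysis chain can be exercised on
    reproducible in-silico experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
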