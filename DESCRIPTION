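Package: digispindle
Title: Digital Spindle Analysis of EB1 Comet Dynamics in 3D
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for microtubule plus-end (EB1-GFP
    comet) dynamics in the mitotic spindle, as observed by volumetric
    lattice light-sheet time-lapse imaging. Generates ground-truth spindle
    geometries and comet trajectories, renders noisy 3D+t fluorescence
    volumes with a Gaussian PSF model, detects comets with sub-voxel
    accuracy (Laplacian-of-Gaussian), links detections into trajectories,
    registers cells into a canonical spindle reference frame (drift
    correction), and classifies trajectories by mean travel speed,
    spherical zone of origin, and travel angle against the spindle axis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
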