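Package: cryoFidReg
Title: Fiducial-Based Registration of 3D Cryo-Fluorescence Volumes to 2D
    Cryo-FIB Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Correlative cryo-light/electron microscopy targeting toolkit.
    Registers fluorescent fiducial microspheres localized in a 3D
    cryo-fluorescence z-stack to their counterparts in a 2D cryo-FIB image
    by least-squares estimation of three Z-Y-X Euler angles under a
    rotate-then-project (orthographic) model. Provides sub-voxel bead
    localization in volumes, the bump-apex center rule for FIB images,
    iterative refinement (outlier rejection and per-marker z optimization),
    held-out and leave-one-out targeting-precision estimation, overlay
    rendering of the fluorescence volume onto the FIB frame, milling-target
    export, and a fully seeded synthetic-scene generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
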