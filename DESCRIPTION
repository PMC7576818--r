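Package: SurfaceParticles
Title: Particle Detection and Contamination Statistics for Tile-Scan
    Microscopy of Exposed Surfaces
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and measurement of particulate contamination on
    coated surfaces imaged by two-magnification tile-scan brightfield
    microscopy. Implements frame-rejection quality control, global and
    locally refined thresholding on the blue channel, per-particle
    measurement (area, centroid, equivalent-ellipse elongation),
    size-class and morphotype classification including drying-halo
    flagging, and contamination statistics: particle densities with
    dispersion, coating-by-holder density summary grids, cumulative
    particle size functions, unpaired t-test coating comparisons,
    long-term fractional coverage extrapolation from truncated
    log-normal size laws, and surface-cleanliness classification.
    A synthetic tile-scan generator with planted ground truth makes
    every stage testable without access to the original slides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    png,
    jsonlite,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, QualityControl
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'SurfaceParticles-package.R'
    'detection.R'
    'classification.R'
    'io.R'
    'pipeline.R'
    'scene-spec.R'
    'render.R'
    'stats.R'
    'truncated-lognormal.R'
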