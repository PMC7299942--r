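Package: goldBundle
Title: Registration and Quantification of Immunogold Label on Hair-Cell
    Stereocilia from FIB-SEM Label Volumes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Registers tower-shaped segmented structures (stereocilia and
    kinocilia) from serial FIB-SEM label volumes into a common canonical
    frame and quantifies the three-dimensional distribution of immunogold
    beads on their surfaces. Provides AmiraMesh and multipage TIFF label
    volume I/O, translation-only mutual-information slice alignment,
    principal-component and spherical mean-shift orientation estimation,
    Rodrigues-rotation frame normalization, bead-to-tower association by
    k-nearest-neighbour voting or distance transform, per-row template
    registration, cylindrical (height segment by azimuth sector) bead
    histograms, surface-area-normalized labeling densities, and a synthetic
    bundle generator with ground truth for end-to-end validation.
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
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'amira.R'
    'associate.R'
    'geometry.R'
    'goldBundle-package.R'
    'hull.R'
    'io-tables.R'
    'methods-accessors.R'
    'pipeline.R'
    'plots.R'
    'preprocess.R'
    'quantify.R'
    'simulate.R'
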