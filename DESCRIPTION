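Package: ccquant
Title: Choriocapillaris Quantification from Swept-Source OCTA En Face Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative assessment of the choriocapillaris (CC)
    from repeated swept-source OCT angiography en face images. Implements
    mutual-information driven three-step registration (translation, affine,
    cubic B-spline free-form deformation) and averaging of repeated scans,
    image-quality metrics (global entropy, global standard deviation, local
    texture correlation, PSNR), intercapillary-distance estimation from the
    radially averaged 2-D power spectrum, fuzzy c-means segmentation of flow
    deficits with elbow model selection, flow-deficit morphometric indices
    (density, number, size, aspect-ratio index, complexity index) with
    functional maps, and a synthetic CC phantom generator with known spacing,
    motion, speckle statistics and planted flow deficits for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
biocViews: Visualization, Preprocessing, Alignment, Clustering, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
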