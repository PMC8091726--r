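Package: irfpquant
Title: Objective Quantification of iRFP Tumour Fluorescence from In Vivo
    Imaging TIFFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for platform-independent quantification of near-infrared
    fluorescent protein (iRFP713) tumour signal in small-animal imaging.
    Raw single-channel TIFF images exported from in vivo imaging platforms
    are cropped, optionally sum-binned, normalised to the unit interval and
    rendered as a 3D intensity surface; a horizontal plane cut, initialised
    by Kapur maximum-entropy histogram thresholding and adjustable by the
    user, separates tumour signal from mouse-body background. Measurements
    are taken from the raw, unscaled counts with plane-level background
    subtraction. Companion statistics cover longitudinal fold change,
    coefficient of variance, dilution-series linearity and limit of
    detection, detection heat-tables, saturation screening and detector
    binning. A synthetic-scene generator (mouse-body plateau, Gaussian
    tumour blobs, detector noise, bit-depth clipping, dilution plates,
    phantom repositioning) makes every stage testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'image-io.R'
    'irfpquant-package.R'
    'segmentation.R'
    'quantification.R'
    'series-stats.R'
    'synthetic.R'
    'pipeline.R'
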