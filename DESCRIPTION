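Package: lungfields
Title: Lung-Field Segmentation of Chest Radiographs with a Residual
    CNN-Transformer Network
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for segmenting lung fields in pediatric
    chest radiographs. Raw radiographs acquired on heterogeneous machines
    are harmonized by central-quarter grayscale truncation (windowing to
    the intensity range observed in the central quarter of the image) and
    min-max normalization. Segmentation uses a hybrid encoder-decoder
    network (TransResUNet): a residual CNN encoder producing a three-level
    feature pyramid, a multi-layer transformer bottleneck over patch
    tokens of the deepest features, and a skip-connected residual decoder
    with a per-pixel two-class head. Includes a deterministic training
    loop (RMSprop), connected-component and morphological mask
    post-processing, accuracy/sensitivity/specificity/Dice evaluation, a
    seeded synthetic chest-phantom generator for testing and calibration,
    and a command-line interface. The network, including all forward and
    backward passes, is implemented natively on BLAS-backed matrix
    operations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    igraph,
    png,
    tiff,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: ImageSegmentation, Software
RoxygenNote: 7.3.3
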