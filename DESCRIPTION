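Package: cocoonsort
Title: Multi-Station Optical Sorting of Silkworm Cocoons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computational pipeline for automated quality sorting of Bombyx mori
    cocoons. Implements the three optical stations of a cocoon-sorting machine:
    shape and size selection from segmented silhouettes (HSB edge emphasis, Otsu
    binarization, radial outline digitization, generalized Procrustes alignment,
    elliptic Fourier shape descriptors, and a logistic shape classifier),
    outside-stain detection by fixed HSB thresholding with a per-object area
    rule from paired top and bottom views, and alive/dead pupa discrimination
    from a 7x5 photodiode light-transmission matrix. Includes Z-score
    standardization, class balancing, stratified splitting, Monte Carlo cross
    validation, accuracy/recall reporting, a synthetic benchmark generator with
    full ground truth, and an end-to-end sorting cascade with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
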