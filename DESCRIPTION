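Package: dazzlesim
Title: Biomimetic Simulation and Grading of Laser-Induced Visual Interference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how visible-band laser exposure degrades
    human vision. Implements the CIE disability-glare veiling-luminance model
    with age and iris-pigmentation terms, Adrian-style threshold-contrast
    visibility functions, and the derived laser-safety quantities (maximum
    permissible exposure, maximum dazzle exposure, nominal ocular hazard and
    dazzle distances, dazzle angle). Simulates a foveated retina-like detector
    with concentric-ring pixels and logarithmic photoresponse, provides a
    laser-spot image pipeline (Otsu binarization, Canny edge extraction,
    inscribed-ellipse defect compensation, gamma enhancement, least-squares
    Gaussian fitting, biomimetic halo overlay), and grades scenarios into
    interference Levels I-IV with a grey analytic hierarchy process. Includes
    a synthetic spot/scene generator, batch scenario runner and dose-effect
    curve tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
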