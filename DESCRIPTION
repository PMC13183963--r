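Package: cellquant
Title: Label-Free Cell Culture Analytics from Brightfield Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@cellquant.dev", role = c("aut", "cre"))
Description: Trainable, reagent-free analytics for routine cell culture:
    U-Net semantic segmentation of adherent cultures into cell/background
    with confluency percentages, flow-field instance segmentation for
    hemocytometer cell counting with style-vector cell-size regression,
    per-object live/dead viability classification of dye-stained chambers,
    and the surrounding quantitative layer (growth rate and doubling time,
    four-parameter dose-response with IC50, sampling plans, concentration,
    and agreement metrics). Includes a seeded synthetic microscopy-image
    generator with exact ground truth (adherent fields, counting-chamber
    scenes with grid lines and stained dead cells, reference beads, debris,
    defocus blur) so that every model can be trained and validated end to
    end, and a compact CNN engine (convolution, pooling, Adam) implemented
    with 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    minpack.lm,
    jsonlite,
    tiff,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
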