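Package: discgrowth
Title: Growth Deceleration, Hypoxia-Reporter Calibration and Fluorescence
    Quantification for Drosophila Wing Imaginal Discs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for studying growth deceleration in
    Drosophila wing imaginal discs. Fits a self-starting logistic model to
    disc-volume time courses and derives the relative growth rate
    (dV/dt)/V with bootstrap uncertainty ribbons; screens gene expression
    time courses for correlation with the declining growth rate, with
    max-normalisation, Ward (D2) clustering and hypergeometric gene-set
    over-representation; calibrates two-regime (segmented) oxygen-response
    curves of hypoxia reporters to obtain a sensitivity breakpoint and a
    dynamic range; and implements ROI-based fluorescence quantification
    rules (compartment P/A ratios, area fractions, ratiometric red/green,
    trichome density, pupariation T50). A synthetic-data module generates
    every input with known planted truth so all analyses are testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    EBImage,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
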