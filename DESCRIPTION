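Package: mammodense
Title: Automated Mammographic Breast Density Segmentation and BI-RADS
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully automated pipeline for estimating breast density from
    digital mammograms. Includes region-growing pectoral muscle removal,
    dense-tissue segmentation with a conditional generative adversarial
    network (U-Net generator, patch discriminator, selectable MSE / Dice /
    SSIM content losses), percent-density estimation with BI-RADS
    threshold rules, a small convolutional network classifier over binary
    masks, one-vs-rest multi-class evaluation metrics, and a synthetic
    phantom-mammogram generator with exact ground truth so the whole
    pipeline can be exercised without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
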