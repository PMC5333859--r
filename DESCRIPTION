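Package: tgchemo
Title: Chemometric and Kinetic Compositional Analysis of Thermogravimetric Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the chemical (hemicellulose, cellulose, lignin)
    and proximate (volatile matter, fixed carbon, ash) composition of
    lignocellulosic biomass from thermogravimetric (TG) mass-loss curves.
    Provides a pseudo-component thermogram simulator with known ground truth,
    classical kinetic deconvolution of TG curves at fixed boundary temperatures,
    from-scratch principal component regression (PCR) and NIPALS partial least
    squares (PLS) calibration with leave-one-out cross-validation, PRESS-based
    parsimonious factor selection, SEC/SECV/R2/RPD performance metrics, and a
    pipeline that compares the chemometric and kinetic approaches on a common
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
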