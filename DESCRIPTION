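Package: sarjdose
Title: Radiochromic Film Dosimetry and Treatment Analysis for a Shielded
    Small-Animal Irradiation Jig
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the dosimetric commissioning and preclinical use of a
    lead-shielded jig that delivers parallel-opposed tangential kilovoltage
    beams to flank tumours in mice. Builds Hunter-Driffield calibration
    curves relating radiochromic-film red-channel pixel values to absorbed
    dose, converts scanned films to dose maps, quantifies beam profiles
    (80-20% penumbra, field edges, tumour-margin offsets, site-to-site
    uniformity), models the jig analytically (half-value-layer shielding
    transmission, inverse-square dose-rate scaling, exponential depth dose,
    parallel-opposed beam summation, fractionation planning), and analyses
    tumour treatment response (calliper volumes, Kaplan-Meier survival, an
    exact rank-sum test for small groups). A synthetic-data module generates
    film responses, 2-D dose fields, rendered film scans, phantom exposures
    and tumour-growth datasets with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
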