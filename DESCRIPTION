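Package: alphangle
Title: Automated Alpha-Angle Measurement from Proximal Femur Landmark Outlines
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes the alpha angle of the hip from ordered landmark
    coordinates placed around the femoral head and neck on anterior-posterior
    images, and classifies cam morphology (alpha angle >= 60 degrees). A
    least-squares circle is fitted to the femoral head landmarks, the
    narrowest femoral neck width is located by a line-segment search, and the
    point where the outline leaves the circle (the index point) is found
    under four increasingly robust decision rules. Includes inter-rater
    agreement statistics (Lin's concordance correlation coefficient, Cohen's
    kappa with percentage agreement, Bland-Altman limits of agreement, mean
    absolute difference) and a parametric synthetic-hip generator with known
    ground truth for end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
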