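Package: tdch
Title: Tongue Image Colour Analysis with Two-Dimensional Colour Histograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tongue colour from digital photographs in the CIE 1976
    (L*, a*, b*) colour space. Provides gradient-vector-flow snake segmentation
    of the tongue region seeded by a polar edge map, exclusion of dark-root and
    specular-highlight pixels by L* thresholding, least-squares colour
    correction from a 12-patch colour checker, and a 4 x 4 two-dimensional
    colour histogram (TDCH) over (L*, a*) from which seven variables (V1-V7)
    and the V7/V3 redness ratio are extracted. Includes the downstream
    statistical battery (Lilliefors and Shapiro-Wilk normality tests,
    Mann-Whitney U, paired t) and cross-validated classification of the TDCH
    variables, plus a synthetic tongue-phantom and cohort generator so the
    whole pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    grDevices,
    jsonlite,
    yaml,
    png,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    nortest,
    optparse
Config/testthat/edition: 3
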