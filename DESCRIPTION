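Package: cleftmorph
Title: Quantification of Secondary-Palate Clefts from Neonatal CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated morphometry of congenital secondary-palate clefts in
    neonatal-dog-scale computed tomography. Segments bone by Hounsfield-unit
    thresholding, extracts a triangulated iso-surface, isolates the oral
    (ventral) sheet of the hard palate, detects cleft outlines while bridging
    sub-millimetre unfused sutures, virtually fills each defect with a
    curvature-matched tensor-product spline patch, trims the patch to the
    defect outline, and reports cleft surface area, total hard-palate area,
    percentage, length and width, together with the four-region numerical
    cleft classification code. Includes a synthetic CT phantom generator with
    analytic surface-area oracles so the whole pipeline is testable without
    clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    readr,
    rlang,
    generics,
    ggplot2,
    pracma,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
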