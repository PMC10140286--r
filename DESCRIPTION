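Package: facedysm
Title: Quantifying Facial Dysmorphology from 2D Landmarks with Euclidean
    Distance Matrix Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based quantification of facial dysmorphology in rare
    disorders. Reads and writes 18-landmark 2D facial configurations (CSV and
    TPS), maps standard 68-point face-detector output onto the 18-landmark
    anatomical scheme, and validates automatic landmarks against manual ones by
    root-mean-square error. Implements centroid-size-scaled Euclidean Distance
    Matrix Analysis (EDMA): form matrices of all unique interlandmark
    distances, relative differences between patient and control mean forms,
    and a two-sample nonparametric bootstrap confidence-interval test per
    distance. Summarises each contrast as a Facial Dysmorphology Score (FDS,
    the percentage of significantly different distances) and assesses its
    significance with a staggered pseudo-subsample simulation. A synthetic
    landmark-cohort generator with documented syndrome-like effect presets
    makes the whole pipeline testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
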