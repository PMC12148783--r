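Package: sabrcheck
Title: Online Pre-Treatment Dose Assessment for Prostate SABR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative pre-treatment patient setup assessment in
    prostate stereotactic ablative body radiotherapy (SABR). Superimposes a
    planned dose distribution onto daily cone-beam CT organ-at-risk contours
    using the online rigid-registration couch shift, computes per-fraction
    dose-volume histogram (DVH) metrics, classifies them against a two-tier
    clinical goal table (optimal / minor / major violation), and evaluates
    bladder and rectum decision-tree setup rules. Includes a local gamma-index
    engine for dose-distribution comparison, a minimal DICOM-RT reader/writer
    (RTDOSE, RTSTRUCT, translation-only REG), and a synthetic pelvic phantom
    generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
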