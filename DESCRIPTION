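Package: brachyqa
Title: Dose-Volume Histogram Quality Assurance for Brachytherapy
    Treatment Planning Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Independent hand-calculation engine and pass/fail framework
    for commissioning, upgrade, and annual quality-assurance testing of
    dose-volume histograms (DVH) produced by brachytherapy treatment
    planning systems.  Implements the AAPM TG-43 point-source and
    line-source dose formalisms for sealed sources (LDR I-125 seeds and
    HDR Ir-192 sources ship as presets), converts source-distance isodose
    surfaces into partial volumes of a narrow cuboid QA structure with
    curvature correction, compares TPS-exported cumulative DVH curves
    against the reference tables using per-radius "actual variance" and
    "average variance" metrics with 5 and 2 percentage-point tolerances,
    and includes a desk-scale synthetic planning-system simulator
    (voxelized dose grid plus DVH binning) for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
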