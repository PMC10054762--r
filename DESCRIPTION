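Package: microstab
Title: Bioanalytical Method Validation and Microsomal Metabolic Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for LC-MS/MS bioanalytical method validation and in vitro
    metabolic stability assessment in liver microsomes. Fits unweighted
    calibration lines on analyte/internal-standard peak-area ratios,
    back-calculates unknowns, and computes the standard validation
    statistics: per-level accuracy, precision (%RSD) and recovery,
    intra/inter-batch quality-control summaries, extraction recovery,
    matrix effect and internal-standard normalized matrix effect, LOD/LOQ
    from the dispersion of calibration intercepts, and a quantitative
    carryover check with configurable acceptance thresholds. Substrate
    depletion time courses are normalized to percent remaining, the
    log-linear phase is selected manually or automatically, and first-order
    kinetics yield the in vitro half-life, intrinsic clearance scaled to
    whole-body units, and a low/intermediate/high clearance class. A
    synthetic-data generator emulates calibration standards, QC replicates,
    paired matrix-effect sample sets and biphasic depletion curves so every
    pipeline stage is testable without instrument output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
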