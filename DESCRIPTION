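Package: bzblock
Title: Wavefront-Curvature Model of Unidirectional Conduction Block in the
    Infarct Border Zone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative model of functional conduction block in the
    postinfarction border zone. Thin-to-thick transitions in border-zone
    thickness impose convex wavefront curvature that slows and, at short
    coupling intervals, blocks conduction; the package computes the
    thickness-change ratio and curvature fields, the rate-dependent critical
    block threshold from a circular-arc calibration, and simulates
    premature-stimulation activation maps on synthetic isthmus geometries,
    including unidirectional block line formation and the first reentry
    cycle of figure-of-eight ventricular tachycardia. Circuit metrics
    quantify the overlap between the unidirectional block line and the
    reentry isthmus.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
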