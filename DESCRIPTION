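Package: rhythmscan
Title: Cosinor Rhythmometry of Wrist Temperature and Phenome-Wide
    Time-to-Event Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying diurnal rhythms of wearable wrist skin
    temperature and their association with future disease onset.
    Implements raw-sensor-unit conversion, non-wear masking and quality
    control of epoch-level temperature series; per-participant 24-hour
    cosinor fits (mesor, amplitude, acrophase); multiplicative device-
    cluster equalization, seasonal log-amplitude correction and a
    permutation-based device calibration diagnostic; ICD-10 to PheCODE
    mapping with exclusion phenotypes and landmark (lagged-entry)
    risk-set construction; a phenome-wide Cox proportional-hazards scan
    with robust standard errors, Benjamini-Hochberg and Bonferroni
    multiplicity control, sex and age interaction screens, Schoenfeld
    diagnostics, device-cluster sub-cohort validation, and a
    simulation-based power analysis; plus atlas-style reporting
    (matched case-control traces, risk by amplitude stratum) and a
    fully synthetic cohort generator with known ground truth for
    end-to-end verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
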