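Package: infraslow
Title: Infra-Slow Global BOLD Activity, CSF Coupling, and Propagating
    Wave Analysis for Resting-State fMRI Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying infra-slow (< 0.1 Hz) global brain
    activity in resting-state fMRI. Extracts the global BOLD (gBOLD)
    signal and a cerebrospinal-fluid (CSF) inflow signal, quantifies
    their cross-correlation coupling at a fixed lag, maps parcel-level
    gBOLD presence and regional BOLD-CSF coupling, detects and
    classifies infra-slow waves propagating along the cortical
    principal gradient, computes framewise-displacement motion metrics,
    and runs the cohort-level statistics relating these measures to
    menopause timing and episodic-memory scores. A seeded synthetic
    cohort generator emulates the statistical structure of an
    access-restricted aging cohort so the full pipeline can be run and
    tested without any data download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
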