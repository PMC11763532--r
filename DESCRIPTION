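Package: serorad
Title: Temporal ATR-FTIR Profiling of Dehydrating Serum Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Label-free infrared serum assay built on time-resolved attenuated
    total reflection Fourier-transform infrared (ATR-FTIR) spectra of a serum
    droplet drying on a germanium crystal. Implements relative absorption
    difference (RAD) temporal profiles, RAD gaps for five chemometric
    peak-height indices (hydrophobicity, hydrophilicity, albumin, lactate, IgG
    glycosylation), the serum hydrophobicity index (HPI) with triglyceride
    interference correction, a prognosis prediction function combining the
    five gaps, a paired normalized clinical biomarker score, cohort statistics
    (median/IQR, Mann-Whitney), and a synthetic dehydration-series simulator
    with known ground truth for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
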