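Package: eitrm
Title: Electrical Impedance Tomography Analysis of Lung Recruitment
    Maneuvers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for thoracic electrical impedance
    tomography (EIT) recordings around lung recruitment maneuvers:
    breath segmentation from the global impedance waveform, per-breath
    tidal images, functional lung masks, the global inhomogeneity (GI)
    index, four-band regional ventilation (delta-Z per region of
    interest), EIT-estimated regional compliance, end-expiratory lung
    impedance, and normality-gated paired before/after statistics.
    Includes a seeded synthetic EIT and ventilator simulator of a supine
    ARDS thorax with a gravity-dependent collapse gradient and
    recruitment/derecruitment dynamics, so the full pipeline is testable
    without animal or device data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
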