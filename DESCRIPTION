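Package: mzcanvas
Title: Headless Interrogation of LC-MS/MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for interactive-grade interrogation of
    LC-MS/MS proteomics data: theoretical peptide fragment calculation and
    spectrum annotation, MS1 isotopic feature detection with MS/MS linkage,
    pluggable spectral pre-processing (de-isotoping, charge reduction,
    diagnostic-ion filtering) with forensic provenance records, a relational
    SQLite store for peptide-spectrum matches, reporter-ion quantification
    with isotopic impurity correction, and a provenance notebook that keeps
    every sequence-assignment decision reproducible without the raw files.
    Ships a deterministic synthetic LC-MS run generator used as ground truth
    throughout the test suite, and an 'mzcanvas' command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mzR,
    DBI,
    RSQLite,
    digest,
    jsonlite,
    xml2,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
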