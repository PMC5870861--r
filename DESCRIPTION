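Package: spec2isa
Title: Automated Instrument Metadata Capture from mzML, imzML and nmrML into ISA-Tab
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts instrument and acquisition metadata from open
    mass-spectrometry (mzML, imzML) and NMR (nmrML) XML files by resolving
    controlled-vocabulary parameters against OBO ontologies (PSI-MS,
    imagingMS, nmrCV), and assembles the result into validated ISA-Tab
    (Investigation/Study/Assay) metadata stubs suitable for MetaboLights
    submission, plus a canonical JSON export for pipeline integration.
    Includes a deterministic synthetic fixture generator for the three file
    formats and a structural ISA-Tab validator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
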