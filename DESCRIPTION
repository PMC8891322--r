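Package: petbids
Title: Parse, Validate and Generate PET Brain Imaging Datasets in the BIDS Layout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with positron emission tomography (PET)
    neuroimaging datasets organised in the Brain Imaging Data Structure
    (BIDS) layout. Parses and composes entity-based file names (including
    the PET-specific tracer, reconstruction and blood-recording entities),
    reads and writes PET JSON sidecars and arterial blood recording pairs
    (JSON metadata plus TSV sample tables), enforces the single
    reference-time-scale convention with radioactive decay correction and
    time-zero re-referencing, validates whole dataset trees against an
    error/warning rule taxonomy, and deterministically generates compliant
    synthetic dynamic-PET datasets for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
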