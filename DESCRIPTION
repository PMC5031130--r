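Package: celldrc
Title: Dose-Response Analysis of Live-Cell Imaging Proliferation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Workflow for dose-response analysis of kinetic cell
    proliferation data from live-cell imaging plate readers. Imports plate
    maps and kinetic confluence exports, fits LOESS growth curves per well
    and per treatment group, computes a doubling-normalised cut time from
    the vehicle-control growth curve by detecting the end of the
    exponential phase, extracts growth values at the cut time, fits
    four-parameter log-logistic dose-response models per compound, and
    reports relative EC50 values with tab-delimited exports suitable for
    downstream curve-fitting software. Includes a plate simulator with
    known ground truth for validation and a command-line interface
    mirroring the stepwise workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    xml2,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
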