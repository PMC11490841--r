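Package: oncoflux
Title: Bioenergetic Flux, Isotope-Tracing and Differential-Abundance
    Analysis for Tumour-Progression Cell Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative-metabolism pipeline for adherent cell-line
    panels profiled by extracellular flux analysis, GC/MS stable-isotope
    labelling and quantitative proteomics. Converts plate-format OCR/ECAR
    traces into cell-number-normalised mitochondrial stress-test
    parameters and ATP production rates attributed to glycolysis and
    oxidative phosphorylation; builds natural-abundance correction
    matrices from fragment elemental formulas and inverts them to
    mass-isotopomer distributions and fractional enrichments; applies the
    downstream normalisation and significance stages (Welch tests with
    Benjamini-Hochberg control, relative growth and apoptosis series);
    and ships simulators with serialised ground truth so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
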