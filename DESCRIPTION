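Package: osmoscan
Title: Osmotic-Gradient Ektacytometry Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for osmotic-gradient ektacytometry (osmoscan) data:
    extraction of the seven Lorrca indices (O_min, EI_min, O_EI_max, EI_max,
    O_hyper, EI_hyper, Area) from elongation-index curves with quality-control
    flagging; a synthetic curve generator with exact ground truth for
    validating the extraction; simulators for healthy-donor cohorts and
    red-cell density fractions with the donor-age and cell-age effect
    structure of a reference study; a normality-gated paired-testing and
    linear-model pipeline with age-stratified percentile reference intervals;
    per-cell morphometry from labeled segmentation masks; and gravimetric,
    densitometric and flow-cytometry marker computations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
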