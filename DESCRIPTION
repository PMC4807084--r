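Package: fixntrace
Title: Nitrogen Fixation and Remobilisation Analysis for 15N
    Isotope-Dilution Plant Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying biological nitrogen fixation in
    multi-harvest plant trials labelled with 15N-enriched fertiliser.
    Implements atom-percent-excess correction, total-N-weighted plant-top
    atom excess (WAE), isotope-dilution estimation of the proportion of
    nitrogen derived from the atmosphere (%Ndfa), amounts and rates of N2
    fixed and per-hectare extrapolation; between-harvest nitrogen
    remobilisation (sink/source) accounting; the inferential layer used in
    agronomic trial reports (one- and two-way ANOVA, Duncan's multiple
    range test with compact letter displays, Pearson correlation
    matrices); and a synthetic randomised-complete-block trial generator
    for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
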