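Package: pollenrisk
Title: Dietary Pesticide Exposure and Risk Characterization for Honeybees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing multi-residue pesticide monitoring results from
    honeybee-collected pollen and nectar. Reads residue tables with explicit
    limit-of-quantification (LOQ) censoring semantics, computes caste-specific
    dietary exposure from EFSA Bee Guidance consumption values, characterizes
    acute (LD50) and chronic (LC50) oral risk as toxicity-to-exposure ratios,
    compares treated and control apiaries per timepoint with the Kruskal-Wallis
    test, and simulates zero-inflated LOQ-censored residue studies so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
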