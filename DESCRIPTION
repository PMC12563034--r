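Package: pvprofile
Title: Disproportionality and Correspondence-Analysis Profiling of
    Spontaneous Adverse Drug Reaction Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing drug safety profiles from spontaneous
    reporting system data aggregated at MedDRA system organ class (SOC)
    level. Builds drug-by-SOC contingency tables from individual case
    safety report (ICSR) line lists, computes margin-product expected
    counts and indexed residuals, reporting odds ratios (ROR) with Woolf
    confidence intervals, and a full correspondence analysis with
    contribution-biplot coordinates, dimension retention and top-variable
    selection. Ships the public EudraVigilance oral-anticoagulant
    aggregate counts as fixtures and a synthetic ICSR generator with
    planted profile archetypes so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
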