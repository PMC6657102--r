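Package: smokereg
Title: Build a Smokers' Registry from Free-Text Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An informatics pipeline that extracts smoking behaviors from
    free-text clinical notes. A hotspot-windowed linear support vector
    machine classifies each note into one of five smoking-status classes
    (never, former, current, smoker temporality unknown, unknown); for
    notes classified into a smoker category, a tiered rule set extracts
    pack-year history (complete, computed from partial quantities, or
    partial) and smoking-cessation dates, and the results are assembled
    into de-identified and identified registry tables. Includes a
    deterministic synthetic-note generator for end-to-end testing and an
    evaluation suite (per-class precision/recall/F1, micro-F1,
    sensitivity/specificity, ever-smoker merging, and two-by-two
    extraction evaluation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
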