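Package: bopmap
Title: Construction and Quality Control of Branded Food Composition Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building a branded food composition database from
    "Back of Pack" (BOP) nutrition labels. Cleans branded nutrient records
    (non-food screening, plausibility cut-offs, decimal-shift and salt/sodium
    swap detection, multi-pack collapsing), maps branded items to generic
    reference food codes by ranking summed percentage differences on the four
    labelling macronutrients, enumerates two-group blends on a percentage
    grid, populates micronutrients by allocation-weighted blending, audits
    declared values against EU food-labelling tolerance bands, runs
    per-food-group range quality control with a resolution workflow, derives
    portion-size options, and simulates synthetic branded and generic catalogs
    with injected data-entry errors for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
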