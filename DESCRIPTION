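Package: nutridense
Title: Nutrient-Density Scoring of Foods and One-Day Diets with the NRF9.2 Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dietary nutrient-density profiling built around the
    NRF9.2 (Nutrient-Rich Food) index: score individual foods and whole
    one-day diets per 100 kcal, evaluate diet adequacy through nutrient
    adequacy ratios (NAR) and the mean adequacy ratio (MAR), profile
    macronutrient energy-supply ratios against recommended bands, assign
    within-food-group quartile points, construct diets that follow the
    Chinese food guide pagoda (2022) block quantities, and render the
    resulting block-coloured pagoda with an energy label as deterministic
    SVG. Ships the Chinese Dietary Reference Intake presets the index
    requires and a synthetic food generator for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
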