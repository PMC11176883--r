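Package: eldermeal
Title: Knowledge-Graph-Based Combo-Meal Recommendation and Dietary
    Evaluation for Older Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a food knowledge graph (dishes, ingredients, ingredient
    categories, nutrients, diseases and six typed relations), reasons over it
    with first-order inference rules, and produces disease-aware, preference-
    aware combo-meal recommendations for community-dwelling older adults.
    Includes dietary-quality scoring (a 0-9 dietary diversity score and a
    configurable 0-110 guideline diet-quality index), a seeded synthetic
    food-database and cohort generator, and a simulated 30-day intervention
    harness with paired and Welch t comparisons and a repeated-measures
    sample-size calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
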