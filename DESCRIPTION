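Package: dietsub
Title: Nutrient-Density-to-Cost Ranking and Diet Substitution Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling healthier, lower-cost diets by food-category
    substitution. Food categories are profiled with the Nutrient Rich Food
    index (NRF9.3) expressed per 100 kcal, costed per 100 kcal from
    supermarket price samples, ranked by their nutrient-density-to-cost
    ratio, and classified by NOVA processing level and discretionary status.
    Household 24-h-recall-style intakes are aggregated to diet profiles for
    four-person reference households stratified by ethnicity and
    socioeconomic status; categories in the bottom three ratio quartiles are
    replaced with top-quartile like-for-like alternatives and discretionary
    intake is eliminated. Diet quality (HEIFA-2013-style adult and
    DICE-style child indices), weekly cost, affordability against OECD
    equivalized income, GST counterfactuals, and NOVA distributions are
    reported, with unpaired t-tests, Benjamini-Hochberg adjustment, and a
    change-score linear model. A seeded synthetic-data module emulates the
    composition, price, and recall inputs so the full pipeline runs with no
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
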