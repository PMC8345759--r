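# dietsub

Substitution modeling of healthier, lower-cost diets for New Zealand-style
reference households.

Food price is one of the strongest barriers to a healthy diet, and it bears
hardest on low-income households. `dietsub` implements a dietary and
economic modeling protocol that asks: which food categories deliver the
most nutrition per dollar, and what happens to diet quality, cost, and
affordability when a household's current diet is rebuilt around them? It is
aimed at nutrition and public-health researchers who want a tested,
reproducible implementation of nutrient-density-to-cost ranking and
rule-based diet substitution, with all inputs replaceable by real
food-composition, price, and dietary-survey data.

## The model

**Nutrient profiling.** Each representative food is scored with the
Nutrient Rich Food index NRF9.3, expressed per 100 kcal:

    NRF9.3 = Σ_{i∈9} min(n_i / DV_i, 1)·100 − Σ_{j∈3} (l_j / MRV_j)·100

with nine qualifying nutrients (protein, fiber, vitamins A, C, E, calcium,
iron, magnesium, potassium) capped at 100% of their daily value, and three
uncapped limiting nutrients (saturated fat, added sugars, sodium) as a
percentage of their maximum reference value. Cost per 100 kcal comes from
supermarket price samples (2 supermarkets × 2 SES areas per food). The
**nutrient-density-to-cost ratio** of a food is

    ratio = max(0, NRF9.3/100 kcal ÷ NZD/100 kcal)

and a category's ratio is the *mean of its foods' ratios* (not the ratio of
the means). Categories are ranked and split into quartiles (top quartile =
"nutrient dense, low cost"; with 61 categories the top quartile holds 16).

**Substitution.** Diet categories in the bottom three quartiles are
replaced like-for-like: by the best same-core-group top-quartile category
(preferring configured subtype pairs such as refined bread → fortified
wholegrain bread), else the top-ranking second-quartile category of the
group (this is how full-fat milk falls back to skim milk, since no dairy
reaches the top quartile), else by the fixed most-lacking-group hierarchy
fruit > vegetables > grains > dairy > meat. Discretionary foods (150-kcal
servings) are eliminated, converting into core servings of equal energy.

**Evaluation.** Household diets for four-person reference households
(adult male and female 31–50 y, boy 11–14 y, girl 7–10 y) across six
ethnicity × SES strata are aggregated from 24-h-recall-style records and
scored with an 11-component adult diet-quality index (HEIFA-2013-style) and
a 13-component child index (DICE-style), each out of 100. Weekly diet cost
is expressed as a percentage of the OECD-equivalized household income
(affordability), NOVA processing-level distributions are tallied, and
current vs. healthier diets are compared with unpaired pooled-variance
t-tests, Benjamini–Hochberg adjustment (significance at adjusted p <
0.005), and a change-score linear model.

A seeded synthetic-data module generates composition, price, coding, and
recall inputs with the study's full structure (61 categories × 3
representative foods, 12 price samples per category, six household strata),
so the entire pipeline runs and is testable without any restricted survey
microdata.

## Worked example

```r
library(dietsub)

cfg  <- validate_config()                       # shipped default config
spec <- scenario_spec(seed = 17, n_households_per_stratum = 8)
res  <- run_pipeline(spec, cfg)

head(res$ranking[, c("category_id", "mean_nrf", "mean_cost", "ratio",
                     "quartile", "nova")], 5)
#>   category_id              mean_nrf mean_cost ratio quartile nova
#> 1 fruit_juices                264.     0.657   401.        1 processed
#> 2 orange_yellow_vegetables    271.     0.847   320.        1 unprocessed
#> 3 other_vegetables            401.     1.26    319.        1 unprocessed
#> 4 nuts_seeds                   35.2    0.118   298.        1 unprocessed
#> 5 oils                         10.3    0.0410  252.        1 culinary
```

Fruit juices top the ranking (cheap for a high NRF), oils are the cheapest
energy at NZD 0.04/100 kcal, and the top quartile mixes unprocessed,
ultra-processed, processed, and culinary categories. Summarizing the
modeled households:

```r
dplyr::summarise(res$households,
                 cost_week = mean(cost_week),
                 affordability = mean(affordability),
                 disc = mean(discretionary_servings_day),
                 .by = c(ses, diet))
#>      ses      diet cost_week affordability disc
#> 1    low   current       325          40.2 32.9
#> 2    low healthier       193          23.9  0.0
#> 3 medium   current       307          19.8 26.8
#> 4 medium healthier       173          11.1  0.0

dplyr::summarise(res$dqi, current = mean(dqi_current),
                 healthier = mean(dqi_healthier), .by = index)
#>   index current healthier
#> 1 HEIFA    34.8      72.4
#> 2  DICE    52.1      73.9
```

Substitution eliminates discretionary intake entirely, cuts weekly cost
(and hence improves affordability), and raises both adult and child
diet-quality scores — the qualitative signature of the protocol. Individual
operations are exposed directly:

```r
affordability(191.0, 808)   # 23.64 — weekly cost as % of adjusted income
adjust_income(404, 2)       # 808  — OECD factor for a 4-person household
remove_gst(4.33, 0.15)      # 3.765 — GST-exclusive counterfactual price
```

## Limitations

The shipped fixtures are synthetic: calibrated to the published cost and
nutrient-density ranges and intake patterns, but not a substitute for the
real food-composition database, price survey, or nutrition-survey
microdata. Absolute diet-quality score levels depend on the original
instruments' cut-points and are config approximations; see the methods
vignette (`vignettes/diet-substitution-modeling.Rmd`) for the full account
of assumptions and design choices.
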