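---
title: "Diet substitution modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet substitution modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietsub)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the tunable parameters, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations.

## The protocol

The pipeline has three stages.

1. **Profile and rank.** Every representative food gets an NRF9.3 score
   per 100 kcal and a cost per 100 kcal; their quotient, floored at zero,
   is the nutrient-density-to-cost ratio. Categories aggregate their
   foods (normally three per category) and are ranked into quartiles.
2. **Substitute.** Household diets, aggregated from per-member
   24-h-recall records, have their bottom-three-quartile categories
   replaced with top-quartile like-for-like alternatives; discretionary
   intake is eliminated.
3. **Evaluate.** Diet quality indices, weekly cost, affordability against
   OECD-equivalized income, NOVA processing distributions, and statistics
   comparing current with healthier diets.

## The NRF9.3 index and its parameters

The index sums nine qualifying-nutrient subscores, each the percentage of
a daily value (DV) achieved per 100 kcal and *capped at 100*, and
subtracts three limiting-nutrient subscores, the *uncapped* percentage of
a maximum reference value (MRV). Capping the qualifying side prevents a
single abundant micronutrient from dominating; leaving the limiting side
uncapped lets salty, energy-dense foods go deeply negative, which is
essential for the ranking to penalize them. The basket is the standard
9 + 3; adaptation to a national guideline context happens purely through
the reference values, which are shipped as an editable YAML block
(`nrf:` in `inst/extdata/default_config.yaml`) with units documented
inline. The ratio's zero floor is applied **at the food level, before
category averaging**, so a strongly negative food cannot cancel a
positive sibling within its category.

A category's ratio is the mean of its foods' ratios, *not* the ratio of
the category's mean NRF to its mean cost. The two differ whenever food
costs vary within a category (Jensen's inequality); the package treats
the mean-of-ratios as the defining statistic and a test pins the
distinction with exact arithmetic (foods with NRF 100 at costs 0.25 and
1.00 give a category ratio of 250, not 160).

**Quartile rule.** Quartile 1 takes the top `ceiling(n/4)` categories
(16 of 61), quartile 2 the next `ceiling(n/2) − ceiling(n/4)`, and so on;
ties break by category name ascending so the ranking is deterministic.

## Cost model

Each price sample converts as `price / package_size × 100 / energy × 100`
(NZD per 100 kcal). A food's cost is the pooled mean over all of its
samples; SES areas are not stratified before averaging because the
protocol reports a single mean cost per category. Monetary values are
carried at full precision; rounding (half-up, 1 dp for costs and
percentages, 2 dp for prices) happens only at report time via
`round_half_up()`.

## Households, requirements, income

The reference household is four people: adult male and female 31–50 y, a
boy 11–14 y, and a girl 7–10 y. Member-level recommended servings, fiber
minimum, and sodium maximum are config values chosen so the four-member
sums land on the household targets used throughout the reporting:
vegetables 21.5, fruit 8, grains 22, meat and alternatives 10, dairy and
alternatives 10.5 servings/day; fiber ≥ 100 g/day; sodium ≤ 8450 mg/day.
The per-member split is an editable modeling choice — only the sums are
externally anchored. Weekly equivalized disposable income is NZD 404/week
(low SES) and 775/week (medium SES), multiplied by the OECD adjustment
factor of 2 to scale to the four-person household (808 and 1550);
affordability is weekly diet cost as a percentage of the adjusted income.

## Recall matching and aggregation

Recall items resolve to categories by exact food id, then by lowercase
token-Jaccard similarity of the description against the category
vocabulary (threshold 0.2), then by nearest neighbor on energy-normalized
macronutrient vectors; ties break by category name. The threshold is
deliberately permissive: the matcher is a deterministic stand-in for
manual researcher judgement, and unmatched items are excluded and
counted rather than guessed.

Aggregation uses first-day records only, sums over household members, and
multiplies daily values by seven for weekly figures. Servings derive from
grams via per-core-group serving sizes (75 g vegetables, 150 g fruit,
50 g grains, 250 g dairy, 65 g meat — compromises across guideline
serving tables, editable in config); discretionary categories instead use
a 150-kcal serving through the category's mean energy density. Weekly
diet cost is the sum over categories of weekly servings × cost per
serving, where cost per serving bridges the category's mean cost per
100 kcal through the serving's energy content — energy is the only bridge
the data provides. Macronutrient percent of energy uses Atwater factors
4/9/4 kcal/g; fiber is reported in g/day.

## The substitution algorithm

For each category present in a diet, in order:

1. top-quartile non-discretionary categories map to themselves;
2. otherwise the highest-ratio top-quartile non-discretionary category of
   the same core group, with configured subtype pairs (milk fat levels,
   refined → fortified wholegrain bread, processed → unprocessed
   potatoes, margarine → oils, sugary drinks → fruit juices) taking
   precedence when their target qualifies;
3. otherwise the top-ranking second-quartile category of the group — the
   dairy route, since no dairy category reaches the top quartile while
   skim milk tops quartile 2;
4. otherwise the top-quartile leader of the most-lacking core group, by
   the fixed hierarchy fruit > vegetables > grains > dairy > meat.

Discretionary sources follow steps 2–4 with their coded core-group
analogue and are never chosen as targets (the one discretionary
top-quartile category, processed potato products, is excluded as a
target; the healthier diet must end discretionary-free). Quantity
transfers are one serving for one serving for core sources; discretionary
servings convert by energy (150 kcal each) into target servings, so total
energy may shift while serving accounting stays interpretable. The
hierarchy is evaluated as a fixed published ordering rather than
recomputed per household: no optimization pass is layered on top, which
is consistent with healthier diets still missing most food-group targets.
Two open alternatives — re-ranking "most lacking" per household, and
allowing discretionary targets — were rejected for those reasons.

## Diet quality indices

Both indices are component tables in config, scored out of 100. The adult
index has eleven components: five food groups scored proportionally to
servings/recommendation and capped, a discretionary component declining
linearly to zero at the per-person share of the 11-servings/day household
bound, three negative components scored by threshold bands (saturated fat
and added sugars as %E with bands at 10/12 and 10/15; sodium in mg/day),
and water and alcohol fixed at maximum because those intakes are outside
the model. The cited adult instrument enumerates ten items; the eleventh
is implemented as the discretionary-foods component, the standard reading
of that instrument. The child index has thirteen: the five food groups, a
fruit-and-vegetable variety component (distinct categories consumed / 6),
a wholegrain component proportional to the wholegrain share of grain
servings (categories flagged by name patterns), low-fat/low-sugar/low-salt
bands, and water, tea/coffee, and eating patterns fixed at maximum.

Component *structure* is exact; the cut-points approximate the published
instruments and are editable. Absolute published score levels are
therefore not reproducible without the original instruments and survey
microdata — the tests instead pin structural properties: the
all-recommendations diet scores exactly 100, the empty diet scores
exactly the fixed-component maxima, and scores are monotone in core
servings (increasing) and sodium (non-increasing).

## Statistics

Between-diet comparisons use the unpaired Student's t-test with pooled
variance (Welch available by flag), reported as mean (SEM) over
household-level replicates — the household is the unit of analysis.
P-values are Benjamini–Hochberg adjusted within each report table and
flagged significant at adjusted p < 0.005. When both arms are constant
and equal the p-value is 1 by convention. The change-score model is an
ordinary least-squares fit of healthier-minus-current values on
ethnicity, SES, and age-sex group with all two-way interactions;
rank-deficient designs raise an error naming the aliased terms rather
than silently dropping them.

## The synthetic-data generator

The generator exists so the full pipeline runs, and is testable, with no
access to the restricted inputs. It emulates:

* **Structure** — 61 categories × 3 representative foods (one single-food
  exception category), one price sample per food per supermarket × SES
  area (12 per category, 4 for the exception), six ethnicity × SES strata
  of four-member households.
* **Calibration** — log-normal price and energy-density families centred
  on per-category archetypes, with food costs clipped to
  [0.04, 7.1] NZD/100 kcal and NRF values to [−20.3, 428.5]/100 kcal;
  named archetypes (oils cheapest; green leafy vegetables most expensive
  and most nutrient-dense; processed meat most negative; fruit juices the
  top ratio; skim milk leading quartile 2) sit near their published
  niches, so the computed top quartile reproduces the published 16-member
  set and its 56/31/6/6 NOVA distribution.
* **Intake patterns** — per-stratum household servings/day targets equal
  to the published current-diet pattern (all core groups below their
  summed recommendation; discretionary 23.9–36.9 servings/day by
  stratum), with log-normal person-level noise; staple weighting (milk,
  bread, meat) so the documented substitution routes are exercised;
  children's items never carry food ids, and a configurable fraction of
  adult ids is degraded to stress the matcher.

Log-normal families were chosen because prices and energy densities are
positive and right-skewed; the exact distributions are the generator's
own choice — the emulated protocol specifies none. The default of 24
replicate households per stratum keeps a full run around a minute on one
CPU while giving the t-tests reasonable power; the emulated survey strata
were 3–18 times larger. What the generator does **not** emulate: true
within-category food heterogeneity, correlated price structure across
supermarkets, seasonal price variation, or ethnic dietary-pattern realism
beyond the stratum intensity multipliers. Passing tests therefore
demonstrate the correctness of the algorithms under the study's structure,
not empirical claims about real NZ diets.

## Numerical choices and degenerate inputs

* Zero-energy foods cannot be expressed per 100 kcal; they are excluded
  from ranking with a log message rather than imputed.
* Categories with fewer than three foods load with a warning (the
  single-food breakfast-cereal category is a documented exception);
  categories with no price samples are rejected.
* All tie-breaks (quartile ranking, matching, substitution candidates)
  resolve by ratio descending then name ascending, making every stage
  deterministic given the seed.
* NOVA majority coding breaks ties toward the more-processed label, and
  discretionary ties toward discretionary — the conservative direction
  for healthiness claims.
* Income, cost, and ratio values are carried at full precision
  end-to-end; rounding is a reporting concern only.

## Limitations

The synthetic fixtures are calibrated, not real; absolute cost and DQI
levels from a synthetic run are not comparable to published estimates,
though the qualitative signature (discretionary elimination, universal
cost decrease, diet-quality improvement, unprocessed share roughly
doubling) is reproduced and regression-tested. Mixed dishes, takeaways,
beverages with negligible energy, alcohol, and supplements are outside
the model by design, as is any linear-programming diet optimization or
price-elasticity behavior.
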