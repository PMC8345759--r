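# Default configuration for the diet substitution pipeline.
# Reference values approximate NZ nutrient reference values / guideline
# documents and are editable; the 9 qualifying and 3 limiting NRF nutrients
# must always be present.

nrf:
  qualifying:            # daily value (DV), amount/day
    protein: 50          # g
    fiber: 25            # g
    vitamin_a: 900       # ug RAE
    vitamin_c: 45        # mg
    vitamin_e: 10        # mg
    calcium: 1000        # mg
    iron: 8              # mg
    magnesium: 400       # mg
    potassium: 3800      # mg
  limiting:              # maximum reference value (MRV), amount/day
    satfat: 24           # g
    added_sugars: 50     # g
    sodium: 2300         # mg

amdr:                    # acceptable macronutrient distribution ranges, %E
  protein: [15, 25]
  total_fat: [20, 35]
  carbohydrate: [45, 65]
  added_sugars_max: 10

atwater:                 # kcal per gram; fiber reported g/day, not %E
  protein: 4
  carbohydrate: 4
  total_fat: 9

serving_sizes_g:         # grams per serving, by core food group
  vegetables: 75
  fruit: 150
  grains: 50
  dairy_alternatives: 250
  meat_alternatives: 65
  other: 10

discretionary_serving_kcal: 150
discretionary_limit_per_day: 11   # household bound, servings/day
gst_rate: 0.15
oecd_factor: 2

incomes:                 # weekly equivalized disposable income, NZD/week
  low: 404
  medium: 775

# Four-person reference household (adult male, adult female, boy 11-14,
# girl 7-10).  recommended_servings are servings/day; sums across the four
# members give the household targets (vegetables 21.5, fruit 8, grains 22,
# meat 10, dairy 10.5), fiber minimum 100 g/day, sodium maximum 8450 mg/day.
members:
  - id: adult_male
    sex: male
    age_band: M31_50
    recommended_servings:
      vegetables: 6.0
      fruit: 2.0
      grains: 6.0
      meat_alternatives: 3.0
      dairy_alternatives: 2.5
    fiber_min: 30        # g/day
    sodium_max: 2300     # mg/day
    nutrient_requirements:
      calcium: 1000
      iron: 8
      magnesium: 420
      potassium: 3800
      vitamin_a: 900
      vitamin_c: 45
      vitamin_e: 10
  - id: adult_female
    sex: female
    age_band: F31_50
    recommended_servings:
      vegetables: 5.5
      fruit: 2.0
      grains: 6.0
      meat_alternatives: 2.5
      dairy_alternatives: 2.5
    fiber_min: 25
    sodium_max: 2300
    nutrient_requirements:
      calcium: 1000
      iron: 18
      magnesium: 320
      potassium: 2800
      vitamin_a: 700
      vitamin_c: 45
      vitamin_e: 7
  - id: boy_11_14
    sex: male
    age_band: M11_14
    recommended_servings:
      vegetables: 5.5
      fruit: 2.0
      grains: 6.0
      meat_alternatives: 2.5
      dairy_alternatives: 3.5
    fiber_min: 24
    sodium_max: 2000
    nutrient_requirements:
      calcium: 1300
      iron: 8
      magnesium: 240
      potassium: 3000
      vitamin_a: 600
      vitamin_c: 40
      vitamin_e: 9
  - id: girl_7_10
    sex: female
    age_band: F7_10
    recommended_servings:
      vegetables: 4.5
      fruit: 2.0
      grains: 4.0
      meat_alternatives: 2.0
      dairy_alternatives: 2.0
    fiber_min: 21
    sodium_max: 1850
    nutrient_requirements:
      calcium: 1000
      iron: 8
      magnesium: 160
      potassium: 2500
      vitamin_a: 500
      vitamin_c: 35
      vitamin_e: 6

# Substitution rules ------------------------------------------------------
# Fallback hierarchy when no same-group candidate exists (most-lacking core
# group first, from the national-survey shortfall ordering).
hierarchy: [fruit, vegetables, grains, dairy_alternatives, meat_alternatives]

# Like-for-like subtype pairs (source category -> preferred target); the
# target is used only if it survives the quartile rules.
like_for_like:
  dairy_milk_full: dairy_milk_skim
  refined_bread: wholegrain_bread_fortified
  wholegrain_bread_unfortified: wholegrain_bread_fortified
  cereal_fortified_low_sugar: cereal_fortified_mid_sugar
  cereal_unfortified_high_sugar: cereal_unfortified_low_sugar
  pasta_with_additions: pasta_noodles
  potatoes_processed: potatoes_unprocessed
  savory_snacks: potatoes_unprocessed
  margarine: oils
  discretionary_fats: oils
  yoghurt_full_fat: dairy_milk_skim
  flavored_milk: dairy_milk_skim
  soft_drinks: fruit_juices
  jams_spreads: dried_fruit
  confectionery: dried_fruit
  chocolate: dried_fruit
  meat_pies: nuts_seeds
  cakes_biscuits: wholegrain_bread_fortified

# Item matching ----------------------------------------------------------
match:
  jaccard_threshold: 0.2

# Diet quality indices ---------------------------------------------------
# Eleven-component adult index (HEIFA-2013-style).  Food-group components
# score proportionally to servings/recommendation (capped); negative
# nutrients score by %E / intake bands; water and alcohol are fixed at
# maximum because those intakes are outside the model.
heifa:
  components:
    vegetables:    {max: 10, type: food_group}
    fruit:         {max: 10, type: food_group}
    grains:        {max: 10, type: food_group}
    meat_alternatives:  {max: 10, type: food_group}
    dairy_alternatives: {max: 10, type: food_group}
    discretionary: {max: 10, type: discretionary}
    fats:          {max: 10, type: band, basis: satfat_percent_energy,
                    bands: [10, 12]}          # <10 full, 10-12 half, >12 zero
    added_sugars:  {max: 10, type: band, basis: added_sugars_percent_energy,
                    bands: [10, 15]}
    sodium:        {max: 10, type: band, basis: sodium_mg_day,
                    bands: [2300, 2875]}
    water:         {max: 5, type: fixed}
    alcohol:       {max: 5, type: fixed}

# Thirteen-component child index (DICE-style).  Water, tea/coffee and
# eating patterns are fixed at maximum (excluded from the model).
dice:
  components:
    vegetables:    {max: 10, type: food_group}
    fruit:         {max: 10, type: food_group}
    grains:        {max: 10, type: food_group}
    meat_alternatives:  {max: 10, type: food_group}
    dairy_alternatives: {max: 10, type: food_group}
    fv_variety:    {max: 5,  type: variety, target: 6}
    wholegrains:   {max: 8,  type: wholegrain}
    low_fat:       {max: 5, type: band, basis: satfat_percent_energy,
                    bands: [10, 12]}
    low_sugar:     {max: 5, type: band, basis: added_sugars_percent_energy,
                    bands: [10, 15]}
    low_salt:      {max: 5, type: band, basis: sodium_mg_day,
                    bands: [2000, 2500]}
    water:         {max: 7, type: fixed}
    tea_coffee:    {max: 5, type: fixed}
    eating_patterns: {max: 10, type: fixed}

# Category name substrings flagging wholegrain grain categories (DICE
# wholegrain component).
wholegrain_patterns: [wholegrain, porridge, oats]
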