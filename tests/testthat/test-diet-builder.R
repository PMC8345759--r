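mk_item <- function(member = "adult_male", food_id = NA, desc = "",
                    grams = 100, day = 1L) {
  tibble::tibble(member_ref = member, food_id = food_id,
                 description = desc, grams = grams, day_index = day)
}

test_that("item matching prefers food id, then description, then nutrients", {
  cfg <- default_config()
  ds <- small_dataset()
  ranked <- small_ranked()

  items <- dplyr::bind_rows(
    mk_item(food_id = "fresh_fruit_f1"),
    mk_item(desc = "hot porridge cooked"),
    mk_item(desc = "zzz qqq xxx"))
  items$energy_kcal_100g <- NA_real_
  items$protein <- NA_real_
  items$total_fat <- NA_real_
  items$carbohydrate <- NA_real_
  out <- suppressMessages(match_items(items, ranked, ds, cfg))
  expect_equal(out$category_id[1], "fresh_fruit")
  expect_equal(out$match_method[1], "food_id")
  expect_equal(out$category_id[2], "hot_porridge")
  expect_equal(out$match_method[2], "description")
  expect_equal(out$match_method[3], "unmatched")

  # nutrient-vector fallback: matches the nearest category by Euclidean
  # distance on energy-normalized macros (independent oracle below)
  f <- ds$foods[ds$foods$food_id == "oils_f1", ]
  nut_item <- mk_item(desc = "zzz qqq xxx")
  nut_item$energy_kcal_100g <- f$energy_kcal_100g
  nut_item$protein <- f$protein
  nut_item$total_fat <- f$total_fat
  nut_item$carbohydrate <- f$carbohydrate
  out2 <- suppressMessages(match_items(nut_item, ranked, ds, cfg))
  expect_equal(out2$match_method, "nutrient")
  ref <- as.matrix(ranked[, c("protein", "total_fat", "carbohydrate")]) /
    ranked$mean_energy_kcal_100g * 100
  v <- c(f$protein, f$total_fat, f$carbohydrate) / f$energy_kcal_100g * 100
  d <- sqrt(rowSums(sweep(ref, 2, v)^2))
  nearest <- ranked$category_id[d == min(d)]
  nearest <- nearest[order(ranked$name[d == min(d)])][1]
  expect_equal(out2$category_id, nearest)

  # every item ends matched or counted unmatched
  expect_true(all(out$match_method %in%
                    c("food_id", "description", "nutrient", "unmatched")))
})

test_that("gram-to-serving conversion honors the 150-kcal discretionary rule", {
  cfg <- default_config()
  # discretionary food at 300 kcal/100 g, 150 g eaten -> 450 kcal -> 3.0
  expect_equal(servings_from_grams(150, "other", TRUE, 300, cfg), 3.0)
  # core category with 75 g serving size, 150 g eaten -> 2.0
  expect_equal(unname(servings_from_grams(150, "vegetables", FALSE, 35,
                                          cfg)), 2.0)
  expect_equal(unname(servings_from_grams(0, "fruit", FALSE, 55, cfg)), 0)
})

test_that("household aggregation sums members, days one only, weekly x7", {
  cfg <- default_config()
  ds <- small_dataset()
  ranked <- small_ranked()
  hh <- make_household("nzeo", "low", cfg)

  members <- c("adult_male", "adult_female", "boy_11_14", "girl_7_10")
  # each member eats one 75 g vegetable serving; one member has a
  # second-day record that must be excluded
  items <- dplyr::bind_rows(
    lapply(members, function(m)
      mk_item(m, food_id = "other_vegetables_f1", grams = 75)),
    mk_item("adult_male", food_id = "other_vegetables_f1", grams = 75,
            day = 2L))
  matched <- suppressMessages(match_items(items, ranked, ds, cfg))
  prof <- aggregate_household(matched, hh, ranked, cfg)
  sv <- prof$servings[prof$servings$category_id == "other_vegetables", ]
  expect_equal(sv$servings_day, 4)
  expect_equal(sv$servings_week, 28)
  expect_equal(prof$total_grams_day, 300)

  # empty member triggers a warning; all-empty errors
  expect_warning(aggregate_household(matched[1:2, ], hh, ranked, cfg),
                 "zero items")
  none <- matched[0, ]
  expect_error(suppressWarnings(
    aggregate_household(none, hh, ranked, cfg)), "no recall items")
})

test_that("aggregation is additive, order invariant, and scales linearly", {
  cfg <- default_config()
  ds <- small_dataset()
  ranked <- small_ranked()
  set.seed(9)
  fids <- sample(ds$foods$food_id, 12)
  items <- dplyr::bind_rows(lapply(fids, function(f)
    mk_item("adult_male", food_id = f, grams = runif(1, 20, 300))))
  matched <- suppressMessages(match_items(items, ranked, ds, cfg))

  a <- matched[1:6, ]
  b <- matched[7:12, ]
  pa <- aggregate_household(a, NULL, ranked, cfg)
  pb <- aggregate_household(b, NULL, ranked, cfg)
  pab <- aggregate_household(matched, NULL, ranked, cfg)
  expect_equal(pab$energy_kcal_day, pa$energy_kcal_day + pb$energy_kcal_day)
  expect_equal(pab$cost_week, pa$cost_week + pb$cost_week)
  expect_equal(pab$nutrients_day, pa$nutrients_day + pb$nutrients_day)
  expect_equal(pab$total_grams_day, pa$total_grams_day + pb$total_grams_day)

  # order invariance
  perm <- aggregate_household(matched[sample(12), ], NULL, ranked, cfg)
  expect_equal(perm$cost_week, pab$cost_week)
  expect_equal(sort(perm$servings$category_id),
               sort(pab$servings$category_id))

  # doubling grams doubles servings, energy, cost and weight exactly
  doubled <- matched
  doubled$grams <- doubled$grams * 2
  pd <- aggregate_household(doubled, NULL, ranked, cfg)
  expect_equal(pd$energy_kcal_day, 2 * pab$energy_kcal_day)
  expect_equal(pd$cost_week, 2 * pab$cost_week)
  expect_equal(pd$total_grams_day, 2 * pab$total_grams_day)
  m <- match(pab$servings$category_id, pd$servings$category_id)
  expect_equal(pd$servings$servings_day[m], 2 * pab$servings$servings_day)

  # brute-force category totals from raw rows
  ref <- tapply(matched$grams,
                ds$foods$category_id[match(matched$food_id,
                                           ds$foods$food_id)], sum)
  m2 <- match(names(ref), pab$servings$category_id)
  expect_equal(pab$servings$grams_day[m2], unname(as.numeric(ref)))
})

test_that("macronutrient percent of energy uses Atwater factors", {
  cfg <- default_config()
  nut <- c(protein = 100, total_fat = 0, carbohydrate = 50,
           satfat = 0, total_sugars = 0, added_sugars = 0,
           free_sugars = 0, fiber = 30)
  pe <- macro_percent_energy(nut, 2000, cfg)
  expect_equal(unname(pe["protein"]), 20)     # 100 g x 4 / 2000 x 100
  expect_equal(unname(pe["total_fat"]), 0)
  expect_equal(unname(pe["fiber_g_day"]), 30)
  expect_error(macro_percent_energy(nut, 0, cfg), "energy")

  # closure: when macro energies equal total energy, %E sums to 100
  nut2 <- c(protein = 50, total_fat = 40, carbohydrate = 110,
            satfat = 0, total_sugars = 0, added_sugars = 0,
            free_sugars = 0, fiber = 0)
  energy <- 50 * 4 + 40 * 9 + 110 * 4
  pe2 <- macro_percent_energy(nut2, energy, cfg)
  expect_equal(unname(pe2["protein"] + pe2["total_fat"] +
                        pe2["carbohydrate"]), 100)
})
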