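mk_items <- function(fids, grams = 100, member = "adult_male") {
  tibble::tibble(member_ref = member, food_id = fids, description = "",
                 grams = grams, day_index = 1L)
}

diet_from_foods <- function(fids, grams = 100) {
  cfg <- default_config()
  matched <- suppressMessages(match_items(mk_items(fids, grams),
                                          small_ranked(), small_dataset(),
                                          cfg))
  aggregate_household(matched, NULL, small_ranked(), cfg)
}

test_that("map rules: identity, like-for-like, Q2 dairy fallback, audit", {
  cfg <- default_config()
  ranked <- small_ranked()
  diet <- diet_from_foods(c("fresh_fruit_f1",        # quartile 1 core
                            "dairy_milk_full_f1",    # no Q1 dairy exists
                            "refined_bread_f1",      # subtype pair
                            "margarine_f1",          # pair -> oils (Q1)
                            "potatoes_processed_f1", # discretionary source
                            "confectionery_f1"))     # discretionary source
  map <- build_substitution_map(ranked, diet, cfg)
  entry <- function(src) map[map$source == src, ]

  expect_equal(entry("fresh_fruit")$rule, "identity")
  expect_equal(entry("fresh_fruit")$target, "fresh_fruit")
  # dairy has no top-quartile member: top-ranking second-quartile dairy,
  # which the generator calibrates to be skim milk
  expect_equal(entry("dairy_milk_full")$target, "dairy_milk_skim")
  expect_equal(entry("dairy_milk_full")$rule, "same_group_q2")
  expect_equal(entry("refined_bread")$target, "wholegrain_bread_fortified")
  expect_equal(entry("refined_bread")$rule, "like_for_like_q1")
  expect_equal(entry("margarine")$target, "oils")
  # discretionary potato products fall to their unprocessed core analogue
  expect_equal(entry("potatoes_processed")$target, "potatoes_unprocessed")
  # no target is ever discretionary
  tgt <- ranked[match(map$target, ranked$category_id), ]
  expect_false(any(tgt$discretionary))

  aud <- substitution_audit(map, diet)
  expect_setequal(aud$source, diet$servings$category_id)
  expect_true(all(aud$servings_day_moved > 0))
})

test_that("hierarchy fallback fires when a group is empty in Q1 and Q2", {
  cfg <- default_config()
  # hand-built ranking: dairy only in quartile 3, fruit present in Q1
  ranked <- tibble::tibble(
    category_id = c("fruitA", "vegA", "dairyA", "dairyB"),
    name = c("Fruit A", "Veg A", "Dairy A", "Dairy B"),
    core_group = c("fruit", "vegetables", "dairy_alternatives",
                   "dairy_alternatives"),
    nova = "unprocessed", discretionary = FALSE,
    ratio = c(400, 300, 20, 10), quartile = c(1L, 2L, 3L, 4L))
  diet <- list(servings = tibble::tibble(category_id = "dairyA"))
  map <- build_substitution_map(ranked, diet, cfg)
  # most-lacking hierarchy starts at fruit, which has a Q1 member
  expect_equal(map$target, "fruitA")
  expect_equal(map$rule, "hierarchy")

  # degenerate dataset with no Q1/Q2 candidate anywhere errors
  ranked_bad <- ranked
  ranked_bad$quartile <- c(3L, 3L, 3L, 4L)
  expect_error(build_substitution_map(ranked_bad, diet, cfg),
               "degenerate")
  expect_error(build_substitution_map(dplyr::select(ranked, -"quartile"),
                                      diet, cfg), "not ranked")
})

test_that("map construction is deterministic given the ranked list", {
  cfg <- default_config()
  diet <- diet_from_foods(c("refined_bread_f1", "cheese_f1",
                            "soft_drinks_f2", "processed_meat_f3"))
  m1 <- build_substitution_map(small_ranked(), diet, cfg)
  m2 <- build_substitution_map(small_ranked(), diet, cfg)
  expect_identical(m1, m2)
})

test_that("applying the map clears discretionary intake, keeps Q1/Q2 only", {
  cfg <- default_config()
  ranked <- small_ranked()
  diet <- diet_from_foods(c("dairy_milk_full_f1", "refined_bread_f1",
                            "confectionery_f1", "chocolate_f2",
                            "processed_meat_f1", "fresh_fruit_f2",
                            "savory_snacks_f1"),
                          grams = c(250, 90, 60, 50, 120, 150, 80))
  map <- build_substitution_map(ranked, diet, cfg)
  healthier <- apply_substitution(diet, map, ranked, cfg)

  expect_equal(healthier$discretionary_servings_day, 0)
  post <- ranked[match(healthier$servings$category_id,
                       ranked$category_id), ]
  expect_true(all(post$quartile <= 2))
  expect_true(all(post$quartile[post$core_group != "dairy_alternatives"]
                  == 1))

  # core servings are conserved one-for-one; discretionary convert by energy
  core_src <- diet$servings[!diet$servings$discretionary, ]
  disc_src <- diet$servings[diet$servings$discretionary, ]
  tkcal_disc <- vapply(map$target[match(disc_src$category_id, map$source)],
                       function(id) {
                         r <- ranked[ranked$category_id == id, ]
                         unlist(cfg$serving_sizes_g)[r$core_group] *
                           r$mean_energy_kcal_100g / 100
                       }, numeric(1))
  expected_total <- sum(core_src$servings_day) +
    sum(disc_src$servings_day * cfg$discretionary_serving_kcal / tkcal_disc)
  expect_equal(sum(healthier$servings$servings_day), expected_total)

  # identity fixed point: a pure top-quartile core diet is unchanged
  q1diet <- diet_from_foods(c("fresh_fruit_f1", "rice_grains_f1"))
  q1map <- build_substitution_map(ranked, q1diet, cfg)
  q1heal <- apply_substitution(q1diet, q1map, ranked, cfg)
  expect_equal(sort(q1heal$servings$category_id),
               sort(q1diet$servings$category_id))
  m <- match(q1diet$servings$category_id, q1heal$servings$category_id)
  expect_equal(q1heal$servings$servings_day[m],
               q1diet$servings$servings_day)

  # uncovered category errors
  expect_error(apply_substitution(q1diet, map, ranked, cfg), "cover")
})

test_that("two-category toy substitution matches hand-computed totals", {
  cfg <- default_config()
  ranked <- small_ranked()
  # 150 g of full-fat milk and one 150-kcal serving of confectionery
  conf_e <- ranked$mean_energy_kcal_100g[ranked$category_id ==
                                           "confectionery"]
  diet <- diet_from_foods(c("dairy_milk_full_f1", "confectionery_f1"),
                          grams = c(500, 150 / conf_e * 100))
  map <- build_substitution_map(ranked, diet, cfg)
  healthier <- apply_substitution(diet, map, ranked, cfg)

  # milk -> skim, one-for-one: 500/250 = 2 servings of skim
  skim <- healthier$servings[healthier$servings$category_id ==
                               "dairy_milk_skim", ]
  expect_equal(skim$servings_day, 2)
  # confectionery (1 serving = 150 kcal) -> dried fruit servings of equal
  # energy: 150 / (150 g x dried-fruit density / 100)
  df_e <- ranked$mean_energy_kcal_100g[ranked$category_id == "dried_fruit"]
  df <- healthier$servings[healthier$servings$category_id == "dried_fruit", ]
  expect_equal(df$servings_day, 150 / (150 * df_e / 100))
  # recomputed energy comes from the target categories' densities
  expect_equal(healthier$energy_kcal_day,
               500 * ranked$mean_energy_kcal_100g[
                 ranked$category_id == "dairy_milk_skim"] / 100 +
                 df$servings_day * 150 * df_e / 100)
})
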