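#' Scenario specification for the synthetic generators
#'
#' Defines the study conditions the generators emulate: 61 food categories
#' with three representative foods each (one single-food exception), a
#' 2-supermarket x 2-SES-area price design (12 samples per 3-food
#' category), six ethnicity x SES household strata of four members, and
#' per-stratum intake intensities (core-group servings and discretionary
#' servings per household per day). Costs are calibrated to lie in
#' [0.04, 7.1] NZD/100 kcal and nutrient densities in [-20.3, 428.5]
#' NRF9.3/100 kcal.
#'
#' @param seed Integer seed; the same spec yields identical outputs.
#' @param n_categories Number of categories (default 61).
#' @param foods_per_category Representative foods per category (default 3).
#' @param n_households_per_stratum Replicate households per ethnicity x SES
#'   stratum (default 24).
#' @param id_missing_rate Fraction of adult recall items carrying only a
#'   description (children's items never carry a food id).
#' @param intensities Per-stratum household servings/day targets; a tibble
#'   with columns `ethnicity`, `ses`, `vegetables`, `fruit`, `grains`,
#'   `meat_alternatives`, `dairy_alternatives`, `other`, `discretionary`.
#'   Defaults to the observed current-diet pattern (core groups under
#'   recommendation, discretionary 23.9-36.9 servings/day).
#' @param cost_bounds,nrf_bounds Calibration bounds (NZD/100 kcal;
#'   NRF9.3/100 kcal).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(seed = 1L, n_categories = 61L,
                          foods_per_category = 3L,
                          n_households_per_stratum = 24L,
                          id_missing_rate = 0.15,
                          intensities = default_intensities(),
                          cost_bounds = c(0.04, 7.1),
                          nrf_bounds = c(-20.3, 428.5)) {
  stopifnot(seed == as.integer(seed), n_categories >= 1,
            foods_per_category >= 1, n_households_per_stratum >= 1,
            id_missing_rate >= 0, id_missing_rate <= 1,
            cost_bounds[1] > 0, diff(cost_bounds) > 0, diff(nrf_bounds) > 0)
  structure(list(seed = as.integer(seed),
                 n_categories = as.integer(n_categories),
                 foods_per_category = as.integer(foods_per_category),
                 n_households_per_stratum = as.integer(n_households_per_stratum),
                 id_missing_rate = id_missing_rate,
                 intensities = intensities,
                 cost_bounds = cost_bounds,
                 nrf_bounds = nrf_bounds),
            class = "scenario_spec")
}

# Household servings/day by stratum in the current diet: core groups below
# their summed recommendations (21.5/8/22/10/10.5), discretionary high.
default_intensities <- function() {
  tibble::tribble(
    ~ethnicity, ~ses, ~vegetables, ~fruit, ~grains, ~meat_alternatives,
    ~dairy_alternatives, ~other, ~discretionary,
    "maori",   "low",    7.0,  4.4, 11.9, 5.5, 3.1, 1.5, 36.9,
    "pacific", "low",   10.0,  5.5, 15.5, 6.8, 2.2, 1.4, 31.6,
    "nzeo",    "low",    6.6,  5.1, 11.8, 3.9, 3.5, 1.2, 27.3,
    "maori",   "medium", 6.3,  6.6, 10.9, 5.2, 3.4, 1.3, 27.4,
    "pacific", "medium", 9.2,  5.4, 13.3, 5.5, 2.7, 1.2, 28.2,
    "nzeo",    "medium", 7.8,  5.9, 14.4, 3.6, 3.5, 1.0, 23.9)
}

#' Category archetype table
#'
#' The 61 categories the generator emulates: identifier, display name,
#' core group, NOVA level, discretionary flag, calibration targets for
#' cost (NZD/100 kcal) and nutrient-density-to-cost ratio, energy density
#' (kcal/100 g), and whether the category sits in the top-quartile niche
#' (16 categories: 9 unprocessed, 5 ultra-processed, 1 processed, 1
#' culinary). `single_food` marks the one category generated with a single
#' representative product.
#'
#' @return Tibble with one row per category.
#' @export
category_archetypes <- function() {
  t <- tibble::tribble(
    ~category_id, ~name, ~core_group, ~nova, ~discretionary,
    ~target_cost, ~target_ratio, ~energy, ~top_quartile,
    # -- top-quartile niche (ratios/costs at their published positions) --
    "fruit_juices", "Fruit juices", "fruit", "processed", FALSE,
    0.70, 416.0, 45, TRUE,
    "other_vegetables", "Other vegetables", "vegetables", "unprocessed",
    FALSE, 1.30, 337.9, 35, TRUE,
    "orange_yellow_vegetables", "Orange/yellow vegetables", "vegetables",
    "unprocessed", FALSE, 0.90, 324.3, 40, TRUE,
    "nuts_seeds", "Nuts and seeds", "meat_alternatives", "unprocessed",
    FALSE, 0.12, 303.6, 600, TRUE,
    "hot_porridge", "Hot porridge", "grains", "unprocessed", FALSE,
    0.20, 246.0, 70, TRUE,
    "potatoes_unprocessed", "Potatoes and red kumara unprocessed",
    "vegetables", "unprocessed", FALSE, 0.60, 196.1, 85, TRUE,
    "vegetable_dishes", "Vegetable dishes", "vegetables",
    "ultra_processed", FALSE, 0.60, 183.2, 80, TRUE,
    "pasta_noodles", "Pasta and noodles plain", "grains", "unprocessed",
    FALSE, 0.20, 180.9, 130, TRUE,
    "fresh_fruit", "Fresh fruit", "fruit", "unprocessed", FALSE,
    0.70, 159.1, 55, TRUE,
    "wholegrain_bread_fortified", "Breads and rolls wholegrain fortified",
    "grains", "ultra_processed", FALSE, 0.13, 150.5, 250, TRUE,
    "cereal_unfortified_low_sugar",
    "Breakfast cereal unfortified sugars <=15g/100g", "grains",
    "ultra_processed", FALSE, 0.20, 148.9, 380, TRUE,
    "cereal_fortified_mid_sugar",
    "Breakfast cereal fortified sugars 15-30g/100g", "grains",
    "ultra_processed", FALSE, 0.30, 148.4, 390, TRUE,
    "oils", "Oils", "other", "culinary", FALSE, 0.04, 138.5, 880, TRUE,
    "rice_grains", "Rice and grains", "grains", "unprocessed", FALSE,
    0.10, 136.4, 130, TRUE,
    "potatoes_processed", "Potatoes and red kumara processed",
    "vegetables", "ultra_processed", TRUE, 0.20, 129.2, 180, TRUE,
    "dried_fruit", "Dried fruit", "fruit", "unprocessed", FALSE,
    0.20, 126.8, 300, TRUE,
    # -- lower quartiles --
    "dairy_milk_skim", "Dairy milk skim", "dairy_alternatives",
    "unprocessed", FALSE, 0.25, 95, 37, FALSE,
    "legumes_dried", "Dried legumes", "meat_alternatives", "unprocessed",
    FALSE, 0.30, 85, 120, FALSE,
    "frozen_vegetables", "Frozen vegetables", "vegetables", "processed",
    FALSE, 0.90, 84, 45, FALSE,
    "tomato_sauces", "Tomato-based sauces", "vegetables",
    "ultra_processed", TRUE, 0.80, 80, 85, FALSE,
    "milk_powder", "Milk powder", "dairy_alternatives", "processed",
    FALSE, 0.30, 79, 480, FALSE,
    "refined_bread", "Breads and rolls refined", "grains",
    "ultra_processed", FALSE, 0.15, 78, 255, FALSE,
    "eggs", "Eggs", "meat_alternatives", "unprocessed", FALSE,
    0.50, 75, 150, FALSE,
    "cereal_fortified_low_sugar",
    "Breakfast cereal fortified sugars <15g/100g", "grains",
    "ultra_processed", FALSE, 0.25, 74, 380, FALSE,
    "canned_vegetables", "Canned vegetables", "vegetables", "processed",
    FALSE, 0.80, 70, 50, FALSE,
    "wholegrain_bread_unfortified",
    "Breads and rolls wholegrain unfortified", "grains",
    "ultra_processed", FALSE, 0.20, 69, 250, FALSE,
    "couscous_quinoa", "Couscous and quinoa", "grains", "unprocessed",
    FALSE, 0.40, 65, 130, FALSE,
    "green_leafy_vegetables", "Green leafy vegetables", "vegetables",
    "unprocessed", FALSE, 7.10, 60.35, 25, FALSE,
    "dairy_milk_full", "Dairy milk full/reduced fat", "dairy_alternatives",
    "unprocessed", FALSE, 0.30, 62, 62, FALSE,
    "frozen_fruit", "Frozen fruit", "fruit", "unprocessed", FALSE,
    1.00, 60, 55, FALSE,
    "dairy_milk_substitutes", "Dairy milk substitutes",
    "dairy_alternatives", "ultra_processed", FALSE, 0.45, 55, 45, FALSE,
    "canned_fish", "Canned fish", "meat_alternatives", "processed", FALSE,
    1.00, 54, 150, FALSE,
    "cereal_unfortified_high_sugar",
    "Breakfast cereal unfortified sugars >15-30g/100g", "grains",
    "ultra_processed", FALSE, 0.30, 52, 390, FALSE,
    "margarine", "Margarine", "other", "culinary", FALSE,
    0.18, 45, 720, FALSE,
    "pasta_with_additions", "Pasta with additions", "grains",
    "ultra_processed", FALSE, 0.50, 48, 160, FALSE,
    "fish_meat_eggs_poultry", "Fish meat eggs and poultry",
    "meat_alternatives", "unprocessed", FALSE, 1.20, 45, 190, FALSE,
    "processed_fruit", "Processed fruit in juice", "fruit", "processed",
    FALSE, 0.50, 44, 60, FALSE,
    "yoghurt_reduced_fat", "Yoghurt reduced fat", "dairy_alternatives",
    "ultra_processed", FALSE, 0.50, 43, 75, FALSE,
    "crackers", "Crackers and crispbreads", "grains", "ultra_processed",
    FALSE, 0.50, 40, 420, FALSE,
    "yoghurt_full_fat", "Yoghurt full fat", "dairy_alternatives",
    "unprocessed", FALSE, 0.50, 39, 95, FALSE,
    "liquid_fortified_breakfast", "Liquid/fortified breakfast drinks",
    "dairy_alternatives", "ultra_processed", FALSE, 0.60, 35, 70, FALSE,
    "discretionary_fats", "Discretionary fats", "other", "culinary", TRUE,
    0.20, 34, 700, FALSE,
    "muesli_bars", "Muesli and snack bars", "grains", "ultra_processed",
    TRUE, 0.50, 30, 430, FALSE,
    "cheese", "Cheese", "dairy_alternatives", "processed", FALSE,
    0.80, 29, 400, FALSE,
    "processed_fish_meat_alternatives",
    "Processed fish and meat alternatives", "meat_alternatives",
    "processed", FALSE, 0.90, 25, 160, FALSE,
    "flavored_milk", "Flavored milk", "dairy_alternatives",
    "ultra_processed", TRUE, 0.40, 24, 75, FALSE,
    "ice_cream", "Ice cream and frozen desserts", "dairy_alternatives",
    "ultra_processed", TRUE, 0.50, 22, 210, FALSE,
    "cheese_ultra_processed", "Cheese ultra-processed",
    "dairy_alternatives", "ultra_processed", FALSE, 0.90, 20, 330, FALSE,
    "ultra_processed_fruit", "Canned fruit with added sugars", "fruit",
    "ultra_processed", TRUE, 0.50, 19, 80, FALSE,
    "jams_spreads", "Jams and sweet spreads", "fruit", "processed", TRUE,
    0.30, 20, 270, FALSE,
    "savory_snacks", "Savory snacks", "vegetables", "ultra_processed", TRUE,
    0.60, 18, 500, FALSE,
    "salad_dressings", "Salad dressings and mayonnaise", "other",
    "ultra_processed", TRUE, 0.70, 16, 330, FALSE,
    "meat_pies", "Meat pies and pastries", "meat_alternatives",
    "ultra_processed", TRUE, 0.70, 15, 280, FALSE,
    "cakes_biscuits", "Cakes and biscuits", "grains", "ultra_processed",
    TRUE, 0.40, 12, 430, FALSE,
    "cream_products", "Cream products", "dairy_alternatives", "processed",
    TRUE, 0.60, 12, 340, FALSE,
    "confectionery", "Confectionery", "fruit", "ultra_processed", TRUE,
    0.50, 10, 380, FALSE,
    "chocolate", "Chocolate", "fruit", "ultra_processed", TRUE,
    0.60, 9, 530, FALSE,
    "soft_drinks", "Soft drinks", "fruit", "ultra_processed", TRUE,
    0.40, 8, 40, FALSE,
    "sugar_syrups", "Sugar and syrups", "other", "culinary", TRUE,
    0.10, 5, 390, FALSE,
    "processed_meat", "Processed meat", "meat_alternatives", "processed",
    FALSE, 0.60, 0, 280, FALSE)
  t$target_nrf <- t$target_ratio * t$target_cost
  # published extremes: most negative and most nutrient-dense categories
  t$target_nrf[t$category_id == "processed_meat"] <- -20.3
  t$target_nrf[t$category_id == "green_leafy_vegetables"] <- 428.5
  t$single_food <- t$category_id == "cereal_unfortified_low_sugar"
  t
}

#' Generate synthetic composition, price, and coding tables
#'
#' Draws per-food energy densities, nutrient vectors and package prices
#' from log-normal families around each category archetype, so that
#' computed costs per 100 kcal and NRF9.3 values fall in the calibrated
#' ranges and the named archetypes (oils cheapest, green leafy vegetables
#' most expensive and most nutrient dense, processed meat most negative,
#' fruit juices the top ratio) sit near their niches. Each food receives
#' one price sample per supermarket x SES area (12 per three-food
#' category); one category has a single representative food.
#'
#' @param spec A `scenario_spec`.
#' @return A `food_dataset` (tibbles `foods`, `prices`, `coding`).
#' @export
generate_food_data <- function(spec) {
  arch <- category_archetypes()
  n <- spec$n_categories
  if (n <= nrow(arch)) {
    arch <- arch[seq_len(n), ]
  } else {
    extra <- n - nrow(arch)
    filler <- arch[rep(which(arch$category_id == "confectionery"), extra), ]
    filler$category_id <- paste0("filler_", seq_len(extra))
    filler$name <- paste("Filler category", seq_len(extra))
    filler$single_food <- FALSE
    arch <- dplyr::bind_rows(arch, filler)
  }
  set.seed(spec$seed)

  cfg <- validate_config()
  dv <- unlist(cfg$nrf$qualifying)[NRF_QUALIFYING]
  mrv <- unlist(cfg$nrf$limiting)[NRF_LIMITING]

  foods <- list()
  prices <- list()
  supermarkets <- c("countdown", "paknsave")
  ses_areas <- c("low", "medium")
  for (i in seq_len(nrow(arch))) {
    a <- arch[i, ]
    k <- if (a$single_food) 1L else spec$foods_per_category
    for (j in seq_len(k)) {
      fid <- sprintf("%s_f%d", a$category_id, j)
      energy <- a$energy * rlnorm(1, 0, 0.08)
      cost_f <- a$target_cost * rlnorm(1, 0, 0.08)
      cost_f <- min(max(cost_f, spec$cost_bounds[1]), spec$cost_bounds[2])
      nrf_f <- if (a$target_nrf < 0) {
        a$target_nrf * rlnorm(1, 0, 0.05)
      } else {
        a$target_ratio * cost_f * rlnorm(1, 0, 0.06)
      }
      nrf_f <- min(max(nrf_f, spec$nrf_bounds[1]), spec$nrf_bounds[2])
      nut <- nutrient_vector(nrf_f, a, dv, mrv)
      # per-100kcal fractions -> amounts per 100 g
      per100g <- nut$amount_100kcal * energy / 100
      comp <- as.list(per100g)
      macros <- macro_closure(a, per100g, energy)
      row <- tibble::tibble(
        food_id = fid,
        name = paste(a$name, "product", j),
        category_id = a$category_id,
        energy_kcal_100g = energy)
      foods[[length(foods) + 1]] <- dplyr::bind_cols(row,
                                                     tibble::as_tibble(macros))
      # one sample per supermarket x SES area
      pkg <- sample(c(300, 400, 500, 750, 1000), 1)
      for (sm in supermarkets) {
        for (ses in ses_areas) {
          cost_s <- cost_f * rlnorm(1, 0, 0.05)
          prices[[length(prices) + 1]] <- tibble::tibble(
            food_id = fid, supermarket = sm, ses_area = ses,
            price_nzd = cost_s * energy * pkg / 1e4,
            package_size_g = pkg, date = "2020-12-16")
        }
      }
    }
  }
  coding <- dplyr::select(arch, "category_id", "name", "core_group",
                          "nova", "discretionary")
  structure(list(foods = dplyr::bind_rows(foods),
                 prices = dplyr::bind_rows(prices),
                 coding = coding),
            class = "food_dataset")
}

# Build a per-100-kcal NRF nutrient vector achieving the target index
# value: limiting burden drawn by processing level, qualifying points
# distributed under per-nutrient caps.
nutrient_vector <- function(target_nrf, arch, dv, mrv) {
  lim_scale <- switch(arch$nova,
                      unprocessed = 4, culinary = 8, processed = 15,
                      ultra_processed = 20)
  if (arch$discretionary) lim_scale <- lim_scale * 1.5
  lim <- runif(3, 0.3, 1) * lim_scale          # % of MRV each
  names(lim) <- NRF_LIMITING
  qual_target <- target_nrf + sum(lim)
  if (qual_target < 0) {
    # shrink limits so qualifying points stay non-negative yet the total
    # still reaches a negative target
    lim <- lim * (10 - target_nrf) / sum(lim)
    qual_target <- 10
  }
  caps <- c(protein = 20, fiber = 60, vitamin_a = 100, vitamin_c = 100,
            vitamin_e = 100, calcium = 100, iron = 100, magnesium = 100,
            potassium = 100)
  qual_target <- min(qual_target, sum(caps) - 1)
  w <- runif(9, 0.05, 1)
  names(w) <- NRF_QUALIFYING
  qual <- w / sum(w) * qual_target
  for (pass in 1:20) {
    over <- pmax(qual - caps, 0)
    if (sum(over) < 1e-9) break
    qual <- pmin(qual, caps)
    room <- caps - qual
    if (sum(room) <= 0) break
    qual <- qual + room / sum(room) * sum(over)
  }
  qual <- pmin(qual, caps)
  amount <- c(qual / 100 * dv, lim / 100 * mrv)
  list(amount_100kcal = amount, qualifying_points = sum(pmin(qual, 100)),
       limiting_points = sum(lim))
}

# Fill the non-NRF macro columns (per 100 g) with energy-consistent values.
macro_closure <- function(arch, per100g, energy) {
  fat_share <- switch(arch$core_group,
                      other = if (arch$nova == "culinary") 0.95 else 0.45,
                      meat_alternatives = 0.45,
                      dairy_alternatives = 0.35,
                      0.12)
  if (arch$category_id %in% c("nuts_seeds")) fat_share <- 0.75
  if (arch$category_id %in% c("soft_drinks", "sugar_syrups",
                              "fruit_juices", "jams_spreads",
                              "confectionery")) fat_share <- 0.01
  total_fat <- pmax(fat_share * energy / 9, per100g["satfat"])
  protein <- per100g["protein"]
  carb <- pmax(0, (energy - 4 * protein - 9 * total_fat) / 4)
  added <- min(per100g["added_sugars"], carb)
  natural <- if (arch$core_group == "fruit") 0.8 * (carb - added) else
    0.15 * (carb - added)
  total_sugars <- added + natural
  free_share <- if (arch$category_id %in% c("fruit_juices", "dried_fruit"))
    0.9 else 0
  free <- added + free_share * natural
  list(protein = unname(protein), fiber = unname(per100g["fiber"]),
       vitamin_a = unname(per100g["vitamin_a"]),
       vitamin_c = unname(per100g["vitamin_c"]),
       vitamin_e = unname(per100g["vitamin_e"]),
       calcium = unname(per100g["calcium"]),
       iron = unname(per100g["iron"]),
       magnesium = unname(per100g["magnesium"]),
       potassium = unname(per100g["potassium"]),
       satfat = unname(per100g["satfat"]),
       added_sugars = unname(added),
       sodium = unname(per100g["sodium"]),
       total_fat = unname(total_fat),
       carbohydrate = unname(carb),
       total_sugars = unname(total_sugars),
       free_sugars = unname(free))
}

#' Generate synthetic 24-h recall records for all household strata
#'
#' For each ethnicity x SES stratum, draws the configured number of
#' replicate four-member households. Member intakes are drawn so the
#' stratum-level expected household servings approximate the current-diet
#' pattern (all core groups under their summed recommendation,
#' discretionary intake high), with log-normal person-to-person noise.
#' Adult items carry a resolvable food id except for a configurable
#' missing-id fraction; children's items carry descriptions only, as in
#' the source surveys. A small fraction of members contributes a
#' second-day record, which downstream aggregation must ignore.
#'
#' @param spec A `scenario_spec`.
#' @param dataset The `food_dataset` from [generate_food_data()].
#' @param config A `diet_config`.
#' @return Tibble of recall items with household and stratum columns.
#' @export
generate_recalls <- function(spec, dataset, config = validate_config()) {
  if (!nrow(dataset$coding)) stop("empty category list", call. = FALSE)
  set.seed(spec$seed + 1000L)
  coding <- dataset$coding
  foods <- dataset$foods
  # mean energy density per category, for gram conversion
  e_by_cat <- tapply(foods$energy_kcal_100g, foods$category_id, mean)
  ss <- unlist(config$serving_sizes_g)

  member_ids <- vapply(config$members, function(m) m$id, character(1))
  is_child <- c(FALSE, FALSE, TRUE, TRUE)
  # member share of household servings, from recommended-serving shares
  shares <- vapply(CORE_GROUPS[1:5], function(g) {
    r <- vapply(config$members,
                function(m) m$recommended_servings[[g]] %||% 0, numeric(1))
    r / sum(r)
  }, numeric(4))
  colnames(shares) <- CORE_GROUPS[1:5]

  cats_by_group <- split(coding$category_id[!coding$discretionary],
                         coding$core_group[!coding$discretionary])
  disc_cats <- coding$category_id[coding$discretionary]

  rows <- list()
  for (s in seq_len(nrow(spec$intensities))) {
    stratum <- spec$intensities[s, ]
    for (h in seq_len(spec$n_households_per_stratum)) {
      hid <- sprintf("%s_%s_h%02d", stratum$ethnicity, stratum$ses, h)
      for (mi in seq_along(member_ids)) {
        items <- list()
        for (g in CORE_GROUPS[1:5]) {
          target <- stratum[[g]] * shares[mi, g] * rlnorm(1, 0, 0.2)
          pool <- cats_by_group[[g]]
          k <- min(length(pool), sample(2:3, 1))
          picked <- sample(pool, k, prob = category_weights(pool))
          split_w <- runif(k, 0.2, 1)
          for (ci in seq_len(k)) {
            sv <- target * split_w[ci] / sum(split_w)
            items[[length(items) + 1]] <-
              c(picked[ci], sv * ss[g])
          }
        }
        # the "other" core group (oils/margarine) and discretionary intake
        oth <- stratum$other * 0.25 * rlnorm(1, 0, 0.3)
        oth_cat <- sample(c("margarine", "oils"), 1, prob = c(0.9, 0.1))
        if (oth_cat %in% coding$category_id) {
          items[[length(items) + 1]] <- c(oth_cat, oth * ss["other"])
        }
        disc_target <- stratum$discretionary * 0.25 * rlnorm(1, 0, 0.2)
        kd <- min(length(disc_cats), 3L)
        if (kd > 0) {
          picked <- sample(disc_cats, kd)
          split_w <- runif(kd, 0.2, 1)
          for (ci in seq_len(kd)) {
            sv <- disc_target * split_w[ci] / sum(split_w)
            grams <- sv * config$discretionary_serving_kcal /
              e_by_cat[picked[ci]] * 100
            items[[length(items) + 1]] <- c(picked[ci], grams)
          }
        }
        cat_ids <- vapply(items, `[`, character(1), 1)
        grams <- as.numeric(vapply(items, `[`, character(1), 2))
        # attach a concrete representative food to each item
        fidx <- vapply(cat_ids, function(cid) {
          cand <- which(foods$category_id == cid)
          cand[sample.int(length(cand), 1)]
        }, integer(1))
        keep_id <- !is_child[mi] & runif(length(items)) > spec$id_missing_rate
        n_it <- length(items)
        day <- rep(1L, n_it)
        # occasional second-day record (must be excluded downstream)
        if (runif(1) < 0.15) {
          extra <- sample(n_it, 1)
          cat_ids <- c(cat_ids, cat_ids[extra])
          grams <- c(grams, grams[extra])
          fidx <- c(fidx, fidx[extra])
          keep_id <- c(keep_id, keep_id[extra])
          day <- c(day, 2L)
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          household_id = hid,
          ethnicity = stratum$ethnicity, ses = stratum$ses,
          member_ref = member_ids[mi],
          food_id = ifelse(keep_id, foods$food_id[fidx], NA_character_),
          description = tolower(foods$name[fidx]),
          grams = grams, day_index = day,
          energy_kcal_100g = foods$energy_kcal_100g[fidx],
          protein = foods$protein[fidx],
          total_fat = foods$total_fat[fidx],
          carbohydrate = foods$carbohydrate[fidx])
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Consumption weights: the current diet leans on a few staples per group
# (full-fat milk, refined bread, fish/meat/poultry, fresh fruit, potatoes).
category_weights <- function(pool) {
  staples <- c(dairy_milk_full = 6, refined_bread = 5,
               fish_meat_eggs_poultry = 5, fresh_fruit = 5,
               potatoes_unprocessed = 3, other_vegetables = 3,
               rice_grains = 3, cheese = 2)
  w <- rep(1, length(pool))
  hit <- match(pool, names(staples))
  w[!is.na(hit)] <- staples[hit[!is.na(hit)]]
  w
}

#' Write a synthetic scenario to CSV fixtures
#'
#' @param spec A `scenario_spec`.
#' @param dir Output directory.
#' @param config A `diet_config`.
#' @return Invisibly, the paths written (`composition.csv`, `prices.csv`,
#'   `coding.csv`, `recalls.csv`).
#' @export
write_scenario <- function(spec, dir, config = validate_config()) {
  dataset <- generate_food_data(spec)
  recalls <- generate_recalls(spec, dataset, config)
  paths <- write_dataset(dataset, dir)
  rec_path <- file.path(dir, "recalls.csv")
  readr::write_csv(recalls, rec_path)
  invisible(c(paths, rec_path))
}
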