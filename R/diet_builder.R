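#' Match 24-h recall items to food categories
#'
#' Each recall item is assigned to one category by, in order of preference:
#' (1) an exact `food_id` match against the composition table; (2) the
#' best lowercase token-overlap (Jaccard) match of its description against
#' the category vocabulary (category name plus its foods' names), accepted
#' above a similarity threshold; (3) the nearest category by Euclidean
#' distance between energy-normalized macronutrient vectors (protein, fat,
#' carbohydrate per 100 kcal), when the item carries composition columns.
#' Ties break by category name ascending. Items failing all three routes
#' are flagged unmatched and excluded downstream.
#'
#' @param items Tibble of recall items: `member_ref`, `food_id` (may be
#'   `NA`), `description`, `grams`, `day_index`, and optionally
#'   `energy_kcal_100g`, `protein`, `total_fat`, `carbohydrate` for the
#'   nutrient fallback.
#' @param categories Category tibble from [category_profiles()] or
#'   [rank_categories()].
#' @param dataset The `food_dataset` the categories came from.
#' @param config A `diet_config`.
#' @return `items` with `category_id` and `match_method` columns
#'   (`"food_id"`, `"description"`, `"nutrient"`, or `"unmatched"`).
#' @export
match_items <- function(items, categories, dataset, config) {
  if (any(items$grams < 0)) stop("negative grams in recall", call. = FALSE)
  foods <- dataset$foods
  cat_id <- foods$category_id[match(items$food_id, foods$food_id)]
  method <- ifelse(is.na(cat_id), NA_character_, "food_id")

  vocab <- category_vocabulary(categories, foods)
  need <- which(is.na(cat_id))
  if (length(need)) {
    thr <- config$match$jaccard_threshold %||% 0.2
    desc_tokens <- lapply(tolower(items$description[need]), tokenize)
    for (k in seq_along(need)) {
      i <- need[k]
      sims <- vapply(vocab$tokens, jaccard, numeric(1), b = desc_tokens[[k]])
      best <- max(sims)
      if (is.finite(best) && best >= thr) {
        hit <- which(sims == best)
        hit <- hit[order(vocab$name[hit])][1]
        cat_id[i] <- vocab$category_id[hit]
        method[i] <- "description"
      }
    }
  }

  need <- which(is.na(cat_id))
  macro_cols <- c("energy_kcal_100g", "protein", "total_fat", "carbohydrate")
  if (length(need) && all(macro_cols %in% names(items))) {
    ref <- as.matrix(categories[, c("protein", "total_fat", "carbohydrate")])
    ref <- sweep(ref, 1, categories$mean_energy_kcal_100g, "/") * 100
    for (i in need) {
      e <- items$energy_kcal_100g[i]
      if (is.na(e) || e <= 0) next
      v <- unlist(items[i, c("protein", "total_fat", "carbohydrate")]) /
        e * 100
      if (anyNA(v)) next
      d <- sqrt(rowSums(sweep(ref, 2, v)^2))
      hit <- which(d == min(d))
      hit <- hit[order(categories$name[hit])][1]
      cat_id[i] <- categories$category_id[hit]
      method[i] <- "nutrient"
    }
  }

  method[is.na(cat_id)] <- "unmatched"
  items$category_id <- cat_id
  items$match_method <- method
  n_un <- sum(method == "unmatched")
  if (n_un) message(n_un, " recall item(s) unmatched and excluded")
  items
}

category_vocabulary <- function(categories, foods) {
  food_names <- split(tolower(foods$name), foods$category_id)
  tokens <- lapply(seq_len(nrow(categories)), function(i) {
    id <- categories$category_id[i]
    unique(c(tokenize(tolower(categories$name[i])),
             unlist(lapply(food_names[[id]], tokenize))))
  })
  list(category_id = categories$category_id, name = categories$name,
       tokens = tokens)
}

tokenize <- function(x) {
  t <- unlist(strsplit(x, "[^a-z0-9]+"))
  t[nzchar(t)]
}

jaccard <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Convert grams consumed to servings of a category
#'
#' Core categories use the configured gram serving size of their core food
#' group; discretionary categories use a 150-kcal serving, converted
#' through the category's mean energy density.
#'
#' @param grams Grams consumed.
#' @param core_group Core food group of the category.
#' @param discretionary Logical discretionary flag.
#' @param energy_kcal_100g Category mean energy density.
#' @param config A `diet_config`.
#' @return Servings (vectorized).
#' @export
servings_from_grams <- function(grams, core_group, discretionary,
                                energy_kcal_100g, config) {
  ss <- unlist(config$serving_sizes_g)
  missing <- setdiff(unique(core_group[!discretionary]), names(ss))
  if (length(missing)) {
    stop("no serving size configured for core group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  kcal <- grams * energy_kcal_100g / 100
  ifelse(discretionary,
         kcal / config$discretionary_serving_kcal,
         grams / ss[core_group])
}

#' Aggregate matched recall items to a household diet profile
#'
#' Uses first-day records only (`day_index == 1`), sums intakes across the
#' household's members, and derives daily and weekly servings per category
#' (weekly = 7 x daily), energy, nutrient totals, macronutrient percent of
#' energy, weekly diet cost, and cost per 100 kcal. The weekly cost is the
#' sum over categories of weekly servings times the category's cost per
#' serving (mean cost/100 kcal times the serving's energy content / 100).
#'
#' @param items Matched items (from [match_items()]); unmatched rows are
#'   dropped.
#' @param household A `household`, or `NULL` to aggregate whatever members
#'   appear in `items`.
#' @param categories Category tibble (ranked or unranked).
#' @param config A `diet_config`.
#' @return A `diet_profile` object.
#' @export
aggregate_household <- function(items, household, categories, config) {
  items <- items[items$match_method != "unmatched" & !is.na(items$category_id), ]
  items <- items[items$day_index == 1, ]
  if (!is.null(household)) {
    ids <- vapply(household$members, function(m) m$id, character(1))
    empty <- setdiff(ids, unique(items$member_ref))
    if (length(empty) == length(ids) || !nrow(items)) {
      stop("no recall items for any household member", call. = FALSE)
    }
    if (length(empty)) {
      warning("household member(s) with zero items: ",
              paste(empty, collapse = ", "), call. = FALSE)
    }
    items <- items[items$member_ref %in% ids, ]
  }
  if (!nrow(items)) stop("no recall items to aggregate", call. = FALSE)
  build_profile(items, categories, config)
}

# Shared aggregation core: items must already be matched and day-filtered.
build_profile <- function(items, categories, config) {
  idx <- match(items$category_id, categories$category_id)
  if (anyNA(idx)) stop("item matched to unknown category", call. = FALSE)
  cat_rows <- categories[idx, ]
  items$servings <- servings_from_grams(items$grams, cat_rows$core_group,
                                        cat_rows$discretionary,
                                        cat_rows$mean_energy_kcal_100g,
                                        config)
  items$kcal <- items$grams * cat_rows$mean_energy_kcal_100g / 100

  by_cat <- items |>
    dplyr::summarise(servings_day = sum(.data$servings),
                     grams_day = sum(.data$grams),
                     kcal_day = sum(.data$kcal),
                     .by = "category_id") |>
    dplyr::left_join(
      dplyr::select(categories, "category_id", "name", "core_group", "nova",
                    "discretionary", "mean_cost", "mean_energy_kcal_100g"),
      by = "category_id") |>
    dplyr::mutate(servings_week = 7 * .data$servings_day,
                  serving_kcal = serving_energy(.data$core_group,
                                                .data$discretionary,
                                                .data$mean_energy_kcal_100g,
                                                config),
                  cost_week = .data$servings_week * .data$mean_cost *
                    .data$serving_kcal / 100)

  nut <- as.matrix(categories[idx, ALL_NUTRIENTS]) * items$grams / 100
  nutrients_day <- colSums(nut)
  energy_day <- sum(items$kcal)
  cost_week <- sum(by_cat$cost_week)
  kcal_week <- 7 * energy_day

  grp <- tapply(by_cat$servings_day[!by_cat$discretionary],
                factor(by_cat$core_group[!by_cat$discretionary],
                       levels = CORE_GROUPS),
                sum, default = 0)

  structure(list(
    servings = by_cat,
    servings_by_group = setNames(as.numeric(grp), CORE_GROUPS),
    discretionary_servings_day = sum(by_cat$servings_day[by_cat$discretionary]),
    energy_kcal_day = energy_day,
    nutrients_day = nutrients_day,
    macro_percent_energy = macro_percent_energy(nutrients_day, energy_day,
                                                config),
    cost_week = cost_week,
    cost_per_100kcal = if (kcal_week > 0) cost_week / kcal_week * 100 else 0,
    total_grams_day = sum(items$grams)
  ), class = "diet_profile")
}

serving_energy <- function(core_group, discretionary, energy_kcal_100g,
                           config) {
  ss <- unlist(config$serving_sizes_g)
  ifelse(discretionary,
         config$discretionary_serving_kcal,
         ss[core_group] * energy_kcal_100g / 100)
}

#' Macronutrient percent of energy
#'
#' Percent of energy from protein, total fat, carbohydrate, saturated fat
#' and sugars, using Atwater factors (protein 4, carbohydrate 4, fat
#' 9 kcal/g; sugars at 4). Fiber is reported in g/day, not as percent of
#' energy.
#'
#' @param nutrients_day Named vector of nutrient totals, g/day (sodium mg).
#' @param energy Total energy, kcal/day; must be positive.
#' @param config A `diet_config`.
#' @return Named vector of percent-of-energy values plus `fiber_g_day`.
#' @export
macro_percent_energy <- function(nutrients_day, energy, config) {
  if (energy <= 0) stop("non-positive energy", call. = FALSE)
  at <- config$atwater
  pe <- function(nutrient, factor) {
    unname(nutrients_day[nutrient]) * factor / energy * 100
  }
  c(protein = pe("protein", at$protein),
    total_fat = pe("total_fat", at$total_fat),
    carbohydrate = pe("carbohydrate", at$carbohydrate),
    satfat = pe("satfat", at$total_fat),
    total_sugars = pe("total_sugars", at$carbohydrate),
    added_sugars = pe("added_sugars", at$carbohydrate),
    free_sugars = pe("free_sugars", at$carbohydrate),
    fiber_g_day = unname(nutrients_day["fiber"]))
}

#' @export
print.diet_profile <- function(x, ...) {
  cat("<diet_profile> ", nrow(x$servings), " categories, ",
      round(x$energy_kcal_day), " kcal/day, ",
      round(x$discretionary_servings_day, 1), " discretionary servings/day, ",
      "NZD ", round(x$cost_week, 1), "/week\n", sep = "")
  invisible(x)
}
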