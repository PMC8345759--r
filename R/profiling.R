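#' Rescale a per-100-g nutrient amount to per 100 kcal
#'
#' @param amount_per_100g Nutrient amount per 100 g.
#' @param energy Energy density, kcal per 100 g; must be positive.
#' @return Amount per 100 kcal.
#' @export
#' @examples
#' per_100kcal(5, 50) # 10
per_100kcal <- function(amount_per_100g, energy) {
  if (any(energy <= 0)) {
    stop("zero-energy food: cannot express per 100 kcal", call. = FALSE)
  }
  amount_per_100g * 100 / energy
}

#' Nutrient Rich Food index (NRF9.3)
#'
#' Sums the percent-daily-value contributions of the nine qualifying
#' nutrients, each capped at 100, and subtracts the (uncapped)
#' percent-of-maximum contributions of the three limiting nutrients
#' (saturated fat, added sugars, sodium). Inputs are amounts per 100 kcal,
#' so the index is on the per-100-kcal basis throughout. The result lies in
#' (-Inf, 900] and may be negative for salty or sugary energy-dense foods.
#'
#' @param profile Named numeric vector (or list) of nutrient amounts per
#'   100 kcal covering all 12 NRF nutrients.
#' @param config A `diet_config`.
#' @return The index value.
#' @export
nrf93 <- function(profile, config) {
  profile <- unlist(profile)
  missing <- setdiff(c(NRF_QUALIFYING, NRF_LIMITING), names(profile))
  if (length(missing)) {
    stop("nrf93: missing nutrient(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dv <- unlist(config$nrf$qualifying)[NRF_QUALIFYING]
  mrv <- unlist(config$nrf$limiting)[NRF_LIMITING]
  qual <- sum(pmin(profile[NRF_QUALIFYING] / dv, 1) * 100)
  lim <- sum(profile[NRF_LIMITING] / mrv * 100)
  unname(qual - lim)
}

#' Cost of one price sample per 100 kcal
#'
#' @param price_nzd Price per package, NZD.
#' @param package_size_g Package size, g.
#' @param energy Energy density, kcal per 100 g.
#' @return NZD per 100 kcal.
#' @export
#' @examples
#' cost_per_100kcal(2.00, 500, 200) # 0.20
cost_per_100kcal <- function(price_nzd, package_size_g, energy) {
  if (any(energy <= 0)) {
    stop("zero-energy food: cannot cost per 100 kcal", call. = FALSE)
  }
  if (any(price_nzd <= 0) || any(package_size_g <= 0)) {
    stop("price and package size must be positive", call. = FALSE)
  }
  (price_nzd / package_size_g * 100) / energy * 100
}

#' Profile every food: NRF9.3/100 kcal, cost/100 kcal, and their ratio
#'
#' For each food the composition is rescaled to per 100 kcal and scored with
#' [nrf93()]; cost is the mean of its per-sample costs per 100 kcal (all
#' price samples pooled); the nutrient-density-to-cost ratio is
#' `max(0, nrf / cost)` — the zero floor is applied at the food level.
#' Zero-energy foods are excluded from ranking with a message.
#'
#' @param dataset A `food_dataset`.
#' @param config A `diet_config`.
#' @return Tibble: `food_id`, `category_id`, `nrf_per_100kcal`,
#'   `cost_per_100kcal`, `ratio`.
#' @export
food_profiles <- function(dataset, config) {
  foods <- dataset$foods
  zero <- foods$energy_kcal_100g <= 0
  if (any(zero)) {
    message("excluding ", sum(zero), " zero-energy food(s) from ranking: ",
            paste(foods$food_id[zero], collapse = ", "))
    foods <- foods[!zero, ]
  }
  nut <- as.matrix(foods[, c(NRF_QUALIFYING, NRF_LIMITING)])
  nut_100kcal <- sweep(nut, 1, foods$energy_kcal_100g, "/") * 100
  nrf <- apply(nut_100kcal, 1, nrf93, config = config)

  cost <- dataset$prices |>
    dplyr::inner_join(
      dplyr::select(foods, "food_id", "energy_kcal_100g"),
      by = "food_id") |>
    dplyr::mutate(cost100 = cost_per_100kcal(.data$price_nzd,
                                             .data$package_size_g,
                                             .data$energy_kcal_100g)) |>
    dplyr::summarise(cost_per_100kcal = mean(.data$cost100),
                     .by = "food_id")

  tibble::tibble(food_id = foods$food_id,
                 category_id = foods$category_id,
                 nrf_per_100kcal = nrf) |>
    dplyr::inner_join(cost, by = "food_id") |>
    dplyr::mutate(ratio = pmax(0, .data$nrf_per_100kcal /
                                    .data$cost_per_100kcal))
}

#' Aggregate food profiles to category profiles
#'
#' Category means and sample SDs of NRF/100 kcal and cost/100 kcal are
#' unweighted over the representative foods. The category
#' nutrient-density-to-cost ratio is the mean of the food-level ratios (not
#' the ratio of the means), matching how a category's representative foods
#' are summarized.
#'
#' @param dataset A `food_dataset`.
#' @param config A `diet_config`.
#' @return Tibble, one row per category with coding attached:
#'   `category_id`, `name`, `core_group`, `nova`, `discretionary`,
#'   `n_foods`, `mean_nrf`, `sd_nrf`, `mean_cost`, `sd_cost`,
#'   `mean_energy_kcal_100g`, nutrient means per 100 g, `ratio`.
#' @export
category_profiles <- function(dataset, config) {
  fp <- food_profiles(dataset, config)
  if (!nrow(fp)) stop("no profiled foods", call. = FALSE)
  prof <- fp |>
    dplyr::summarise(
      n_foods = dplyr::n(),
      mean_nrf = mean(.data$nrf_per_100kcal),
      sd_nrf = sd_or_zero(.data$nrf_per_100kcal),
      mean_cost = mean(.data$cost_per_100kcal),
      sd_cost = sd_or_zero(.data$cost_per_100kcal),
      ratio = mean(.data$ratio),
      .by = "category_id")
  comp <- dataset$foods |>
    dplyr::filter(.data$energy_kcal_100g > 0) |>
    dplyr::summarise(
      mean_energy_kcal_100g = mean(.data$energy_kcal_100g),
      dplyr::across(dplyr::all_of(ALL_NUTRIENTS), mean),
      .by = "category_id")
  dataset$coding |>
    dplyr::inner_join(prof, by = "category_id") |>
    dplyr::inner_join(comp, by = "category_id")
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)

#' Assign ratio quartiles to ranked categories
#'
#' Categories are sorted by ratio descending (ties broken by category name
#' ascending); the top `ceiling(n/4)` form quartile 1 ("nutrient dense, low
#' cost"), the next `ceiling(n/2) - ceiling(n/4)` quartile 2, and so on.
#' With 61 categories quartile 1 has 16 members.
#'
#' @param categories Tibble from [category_profiles()].
#' @return The same tibble, sorted, with a `quartile` column (1 = highest
#'   ratio).
#' @export
assign_quartiles <- function(categories) {
  n <- nrow(categories)
  if (!n) stop("no categories to rank", call. = FALSE)
  ranked <- dplyr::arrange(categories, dplyr::desc(.data$ratio), .data$name)
  cuts <- ceiling(n * (1:4) / 4)
  sizes <- diff(c(0L, cuts))        # may contain zeros when n < 4
  ranked$quartile <- rep(1:4, times = sizes)[seq_len(n)]
  ranked
}

#' Rank a dataset: profile categories and assign quartiles
#'
#' Convenience wrapper running [category_profiles()] then
#' [assign_quartiles()]; the result is the Table-2-shaped ranking used by
#' the substitution stage.
#'
#' @inheritParams category_profiles
#' @return Ranked category tibble with `quartile`.
#' @export
rank_categories <- function(dataset, config) {
  assign_quartiles(category_profiles(dataset, config))
}
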