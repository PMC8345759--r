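#' Run the full diet-substitution pipeline on a synthetic scenario
#'
#' Executes the three protocol steps end to end: (1) rank the food
#' categories by nutrient-density-to-cost ratio and code NOVA processing
#' level and discretionary status; (2) build current household diets from
#' recall records and substitute bottom-three-quartile categories with
#' top-quartile like-for-like alternatives to create the healthier,
#' low-cost diets; (3) summarize diet quality, cost, affordability, and
#' NOVA distributions, with per-stratum statistical comparisons.
#'
#' @param spec A `scenario_spec` (or a seed, which is promoted to the
#'   default spec).
#' @param config A `diet_config`.
#' @param out_dir Optional directory; when given, ranking, household
#'   metrics, comparison and NOVA tables plus a run manifest are written
#'   as CSV/JSON.
#' @return A `pipeline_result` list: `ranking`, `households` (per-diet
#'   metric tibble), `dqi` (per-member scores), `comparisons`,
#'   `nova_distribution`, `change_model`, `substitution_audits`.
#' @export
run_pipeline <- function(spec = scenario_spec(), config = validate_config(),
                         out_dir = NULL) {
  if (is.numeric(spec)) spec <- scenario_spec(seed = spec)
  stopifnot(inherits(spec, "scenario_spec"))

  dataset <- generate_food_data(spec)
  ranked <- rank_categories(dataset, config)
  recalls <- generate_recalls(spec, dataset, config)
  matched <- match_items(recalls, ranked, dataset, config)

  child_ids <- c("boy_11_14", "girl_7_10")
  hh_rows <- list()
  dqi_rows <- list()
  audits <- list()
  nova_rows <- list()
  for (hid in unique(matched$household_id)) {
    hh_items <- matched[matched$household_id == hid, ]
    eth <- hh_items$ethnicity[1]
    ses <- hh_items$ses[1]
    household <- make_household(eth, ses, config)
    current <- aggregate_household(hh_items, household, ranked, config)
    map <- build_substitution_map(ranked, current, config)
    healthier <- apply_substitution(current, map, ranked, config)
    audits[[hid]] <- substitution_audit(map, current)

    for (diet in c("current", "healthier")) {
      prof <- if (diet == "current") current else healthier
      d <- processing_distribution(prof$servings$nova,
                                   prof$servings$servings_day)
      d$ethnicity <- eth
      d$ses <- ses
      d$diet <- diet
      nova_rows[[paste(hid, diet)]] <- d
      hh_rows[[paste(hid, diet)]] <- tibble::tibble(
        household_id = hid, ethnicity = eth, ses = ses, diet = diet,
        energy_kcal_day = prof$energy_kcal_day,
        cost_week = prof$cost_week,
        cost_per_100kcal = prof$cost_per_100kcal,
        affordability = affordability(prof$cost_week,
                                      household$adjusted_income),
        discretionary_servings_day = prof$discretionary_servings_day,
        total_grams_day = prof$total_grams_day,
        vegetables = prof$servings_by_group["vegetables"],
        fruit = prof$servings_by_group["fruit"],
        grains = prof$servings_by_group["grains"],
        meat_alternatives = prof$servings_by_group["meat_alternatives"],
        dairy_alternatives = prof$servings_by_group["dairy_alternatives"],
        protein_pe = prof$macro_percent_energy["protein"],
        satfat_pe = prof$macro_percent_energy["satfat"],
        added_sugars_pe = prof$macro_percent_energy["added_sugars"],
        fiber_g_day = prof$macro_percent_energy["fiber_g_day"])
    }

    for (m in config$members) {
      m_items <- hh_items[hh_items$member_ref == m$id, ]
      if (!nrow(m_items)) next
      m_current <- aggregate_household(m_items, NULL, ranked, config)
      m_map <- build_substitution_map(ranked, m_current, config)
      m_healthier <- apply_substitution(m_current, m_map, ranked, config)
      scorer <- if (m$id %in% child_ids) score_dice else score_heifa
      dqi_rows[[paste(hid, m$id)]] <- tibble::tibble(
        household_id = hid, ethnicity = eth, ses = ses,
        member_ref = m$id, age_sex_group = m$age_band,
        index = if (m$id %in% child_ids) "DICE" else "HEIFA",
        dqi_current = scorer(m_current, m, config)$total,
        dqi_healthier = scorer(m_healthier, m, config)$total)
    }
  }
  households <- dplyr::bind_rows(hh_rows)
  dqi <- dplyr::bind_rows(dqi_rows)
  dqi$dqi_change <- dqi$dqi_healthier - dqi$dqi_current

  metrics <- c("energy_kcal_day", "cost_week", "cost_per_100kcal",
               "discretionary_servings_day", "vegetables", "fruit",
               "grains", "meat_alternatives", "dairy_alternatives",
               "fiber_g_day")
  comparisons <- households |>
    dplyr::group_split(.data$ethnicity, .data$ses) |>
    lapply(function(g) {
      compare_table(g[g$diet == "current", metrics],
                    g[g$diet == "healthier", metrics],
                    group = paste(g$ethnicity[1], g$ses[1], sep = "_"))
    }) |>
    dplyr::bind_rows()

  nova <- dplyr::bind_rows(nova_rows) |>
    dplyr::summarise(percentage = mean(.data$percentage),
                     .by = c("ethnicity", "ses", "diet", "nova"))
  change_model <- fit_change_model(dqi$dqi_change, dqi$ethnicity, dqi$ses,
                                   dqi$age_sex_group)

  result <- structure(list(spec = spec, ranking = ranked,
                           households = households, dqi = dqi,
                           comparisons = comparisons,
                           nova_distribution = nova,
                           change_model = change_model,
                           substitution_audits = audits),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(result, out_dir, config)
  result
}

write_pipeline <- function(result, out_dir, config) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(result$ranking[, c("category_id", "name", "core_group",
                                      "nova", "discretionary", "mean_nrf",
                                      "sd_nrf", "mean_cost", "sd_cost",
                                      "ratio", "quartile")],
                   file.path(out_dir, "ranking.csv"))
  readr::write_csv(result$households, file.path(out_dir, "households.csv"))
  readr::write_csv(result$dqi, file.path(out_dir, "dqi.csv"))
  readr::write_csv(result$comparisons, file.path(out_dir, "comparisons.csv"))
  readr::write_csv(result$nova_distribution,
                   file.path(out_dir, "nova_distribution.csv"))
  manifest <- list(seed = result$spec$seed,
                   n_categories = result$spec$n_categories,
                   n_households_per_stratum =
                     result$spec$n_households_per_stratum,
                   config_hash = rlang::hash(unclass(config)),
                   package_version =
                     as.character(utils::packageVersion("dietsub")),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed ", x$spec$seed, ", ",
      nrow(x$ranking), " categories, ",
      length(unique(x$households$household_id)), " households\n", sep = "")
  invisible(x)
}
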