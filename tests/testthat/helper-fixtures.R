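# Shared fixtures, built in code.  Expensive objects are memoised per
# session so multiple test files can reuse them.

fixture_env <- new.env(parent = emptyenv())

default_config <- function() {
  if (is.null(fixture_env$config)) {
    fixture_env$config <- validate_config()
  }
  fixture_env$config
}

# Small synthetic scenario: full structure (61 categories), few households.
small_spec <- function() scenario_spec(seed = 42L,
                                       n_households_per_stratum = 4L)

small_dataset <- function() {
  if (is.null(fixture_env$small_dataset)) {
    fixture_env$small_dataset <- generate_food_data(small_spec())
  }
  fixture_env$small_dataset
}

small_ranked <- function() {
  if (is.null(fixture_env$small_ranked)) {
    fixture_env$small_ranked <- rank_categories(small_dataset(),
                                                default_config())
  }
  fixture_env$small_ranked
}

small_pipeline <- function() {
  if (is.null(fixture_env$small_pipeline)) {
    fixture_env$small_pipeline <- suppressWarnings(suppressMessages(
      run_pipeline(small_spec(), default_config())))
  }
  fixture_env$small_pipeline
}

# Default-scale scenario (the study conditions) for acceptance checks.
default_pipeline <- function() {
  if (is.null(fixture_env$default_pipeline)) {
    fixture_env$default_pipeline <- suppressWarnings(suppressMessages(
      run_pipeline(scenario_spec(seed = 1L), default_config())))
  }
  fixture_env$default_pipeline
}

# Hand-built three-category dataset written to CSV, for loader tests.
# Two foods have exactly known NRF and cost: energy 100 kcal/100 g makes
# per-100-g and per-100-kcal amounts coincide; fiber at its full daily
# value gives an NRF of exactly 100.
write_tiny_csvs <- function(dir) {
  nut0 <- setNames(as.list(rep(0, length(ALL_NUTRIENTS))), ALL_NUTRIENTS)
  f <- function(food_id, name, category_id, energy, ...) {
    over <- list(...)
    nut <- utils::modifyList(nut0, over)
    tibble::as_tibble(c(list(food_id = food_id, name = name,
                             category_id = category_id,
                             energy_kcal_100g = energy), nut))
  }
  comp <- dplyr::bind_rows(
    f("a1", "alpha one", "cat_a", 100, fiber = 25),
    f("a2", "alpha two", "cat_a", 100, fiber = 25),
    f("b1", "beta porridge", "cat_b", 50, protein = 5, sodium = 100),
    f("c1", "gamma treat", "cat_c", 400, added_sugars = 30, satfat = 10))
  prices <- tibble::tibble(
    food_id = c("a1", "a2", "b1", "c1"),
    supermarket = "countdown", ses_area = "low",
    price_nzd = c(2.5, 10, 1, 2), package_size_g = c(1000, 1000, 500, 400),
    date = "2020-12-16")
  coding <- tibble::tibble(
    category_id = c("cat_a", "cat_b", "cat_c"),
    name = c("Alpha vegetables", "Beta porridge", "Gamma treats"),
    core_group = c("vegetables", "grains", "other"),
    nova = c("unprocessed", "unprocessed", "ultra_processed"),
    discretionary = c(FALSE, FALSE, TRUE))
  readr::write_csv(comp, file.path(dir, "composition.csv"))
  readr::write_csv(prices, file.path(dir, "prices.csv"))
  readr::write_csv(coding, file.path(dir, "coding.csv"))
  invisible(file.path(dir, c("composition.csv", "prices.csv",
                             "coding.csv")))
}

tiny_dataset <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_tiny_csvs(dir)
  suppressWarnings(suppressMessages(load_dataset(
    file.path(dir, "composition.csv"), file.path(dir, "prices.csv"),
    file.path(dir, "coding.csv"), quiet = TRUE)))
}

# Minimal hand-constructed diet profile for scoring tests.
manual_diet <- function(servings_by_group, disc = 0, energy = 2000,
                        sodium = 500, satfat_pe = 5, added_pe = 5,
                        servings = NULL) {
  if (is.null(servings)) {
    servings <- tibble::tibble(
      category_id = paste0("c", seq_along(servings_by_group)),
      name = names(servings_by_group),
      core_group = names(servings_by_group),
      discretionary = FALSE,
      servings_day = as.numeric(servings_by_group))
  }
  full <- setNames(numeric(length(CORE_GROUPS)), CORE_GROUPS)
  full[names(servings_by_group)] <- servings_by_group
  structure(list(
    servings = servings,
    servings_by_group = full,
    discretionary_servings_day = disc,
    energy_kcal_day = energy,
    nutrients_day = c(sodium = sodium),
    macro_percent_energy = c(satfat = satfat_pe, added_sugars = added_pe),
    cost_week = 0, cost_per_100kcal = 0, total_grams_day = 0),
    class = "diet_profile")
}
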