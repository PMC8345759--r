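#' Load the composition, price and coding tables into a food dataset
#'
#' Reads the three CSV inputs (per-100-g food composition, per-package price
#' samples, and the category coding of core group, NOVA processing level and
#' discretionary status), validates them against the expected schemas, and
#' reconciles foods to categories. Every food must belong to exactly one
#' coded category, and every category must carry at least one price sample.
#'
#' Expected columns:
#' \describe{
#'   \item{composition}{`food_id`, `name`, `category_id`,
#'     `energy_kcal_100g`, and one column per nutrient (per 100 g).}
#'   \item{prices}{`food_id`, `supermarket`, `ses_area`, `price_nzd`,
#'     `package_size_g`, `date`.}
#'   \item{coding}{`category_id`, `name`, `core_group`, `nova`,
#'     `discretionary`.}
#' }
#'
#' @param composition_path,prices_path,coding_path CSV file paths.
#' @param quiet Suppress the count log message.
#' @return A `food_dataset`: list of tibbles `foods`, `prices`, `coding`.
#' @export
load_dataset <- function(composition_path, prices_path, coding_path,
                         quiet = FALSE) {
  foods <- read_checked(composition_path,
                        c("food_id", "name", "category_id",
                          "energy_kcal_100g", ALL_NUTRIENTS))
  prices <- read_checked(prices_path,
                         c("food_id", "supermarket", "ses_area", "price_nzd",
                           "package_size_g", "date"))
  coding <- read_checked(coding_path,
                         c("category_id", "name", "core_group", "nova",
                           "discretionary"))

  if (anyDuplicated(foods$food_id)) {
    stop("duplicate food_id in composition: ",
         paste(unique(foods$food_id[duplicated(foods$food_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(coding$category_id)) {
    stop("duplicate category_id in coding", call. = FALSE)
  }
  unknown <- setdiff(foods$category_id, coding$category_id)
  if (length(unknown)) {
    stop("category_id in composition but not in coding: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_group <- setdiff(coding$core_group, CORE_GROUPS)
  if (length(bad_group)) {
    stop("unknown core_group: ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  bad_nova <- setdiff(coding$nova, NOVA_LEVELS)
  if (length(bad_nova)) {
    stop("unknown nova level: ", paste(bad_nova, collapse = ", "),
         call. = FALSE)
  }
  if (any(foods$energy_kcal_100g < 0)) {
    stop("negative energy in composition", call. = FALSE)
  }
  nut <- as.matrix(foods[, ALL_NUTRIENTS])
  if (any(nut < 0)) stop("negative nutrient amount in composition",
                         call. = FALSE)
  if (any(prices$price_nzd <= 0) || any(prices$package_size_g <= 0)) {
    stop("price samples must have positive price and package size",
         call. = FALSE)
  }
  orphan <- setdiff(prices$food_id, foods$food_id)
  if (length(orphan)) {
    stop("price samples for unknown food_id: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }

  priced <- foods$category_id[match(prices$food_id, foods$food_id)]
  unpriced <- setdiff(coding$category_id[coding$category_id %in%
                                           foods$category_id], priced)
  if (length(unpriced)) {
    stop("categories without any price sample: ",
         paste(unpriced, collapse = ", "), call. = FALSE)
  }

  n_per_cat <- table(foods$category_id)
  thin <- names(n_per_cat)[n_per_cat < 3]
  if (length(thin) && !quiet) {
    warning("categories with fewer than 3 representative foods: ",
            paste(thin, collapse = ", "), call. = FALSE)
  }
  if (!quiet) {
    message("loaded ", nrow(coding), " categories (",
            length(unique(foods$category_id)), " with foods), ",
            nrow(foods), " foods, ", nrow(prices), " price samples")
  }
  structure(list(foods = foods, prices = prices, coding = coding),
            class = "food_dataset")
}

read_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a food dataset back to CSV
#'
#' Inverse of [load_dataset()]; numeric fields are written at full stored
#' precision so a load/write/load round trip is exact.
#'
#' @param dataset A `food_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "food_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("composition.csv", "prices.csv", "coding.csv"))
  readr::write_csv(dataset$foods, paths[1])
  readr::write_csv(dataset$prices, paths[2])
  readr::write_csv(dataset$coding, paths[3])
  invisible(paths)
}

#' @export
print.food_dataset <- function(x, ...) {
  cat("<food_dataset> ", nrow(x$coding), " categories, ", nrow(x$foods),
      " foods, ", nrow(x$prices), " price samples\n", sep = "")
  invisible(x)
}
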