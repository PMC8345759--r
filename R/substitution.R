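#' Build the like-for-like substitution map for a diet
#'
#' For every category present in the diet the replacement target is chosen
#' by, in order:
#' \enumerate{
#'   \item quartile-1 non-discretionary sources map to themselves
#'     (`identity`);
#'   \item otherwise the highest-ratio quartile-1 non-discretionary
#'     category of the same core food group, preferring a configured
#'     like-for-like subtype pair (e.g. processed potato products map to
#'     unprocessed potatoes) when that pair's target qualifies
#'     (`like_for_like_q1`);
#'   \item otherwise the top-ranking quartile-2 non-discretionary category
#'     of the same core group (`same_group_q2`) — this is how dairy milk
#'     falls back to skim milk when no dairy reaches the top quartile;
#'   \item otherwise the top quartile-1 category of the most-lacking core
#'     group by the fixed hierarchy fruit > vegetables > grains > dairy >
#'     meat (`hierarchy`).
#' }
#' Discretionary sources follow steps 2-4 with their coded core group as
#' the nearest core analogue; discretionary categories are never targets.
#' Construction is deterministic: candidates are ordered by ratio
#' descending then name ascending.
#'
#' @param ranked Ranked category tibble from [rank_categories()].
#' @param diet A `diet_profile` (its categories define the map's domain).
#' @param config A `diet_config`.
#' @return A `substitution_map` tibble: `source`, `target`, `rule`.
#' @export
build_substitution_map <- function(ranked, diet, config) {
  if (!"quartile" %in% names(ranked)) stop("categories are not ranked",
                                           call. = FALSE)
  sources <- diet$servings$category_id
  pool <- ranked[!ranked$discretionary, ]
  pool <- dplyr::arrange(pool, dplyr::desc(.data$ratio), .data$name)
  pairs <- config$like_for_like

  pick <- function(src) {
    row <- ranked[ranked$category_id == src, ]
    if (!nrow(row)) stop("diet category not in ranking: ", src,
                         call. = FALSE)
    if (!row$discretionary && row$quartile == 1) {
      return(c(src, "identity"))
    }
    q1_same <- pool[pool$quartile == 1 & pool$core_group == row$core_group, ]
    preferred <- pairs[[src]]
    if (!is.null(preferred) && preferred %in% q1_same$category_id) {
      return(c(preferred, "like_for_like_q1"))
    }
    if (nrow(q1_same)) {
      return(c(q1_same$category_id[1], "like_for_like_q1"))
    }
    q2_same <- pool[pool$quartile == 2 & pool$core_group == row$core_group, ]
    if (nrow(q2_same)) {
      return(c(q2_same$category_id[1], "same_group_q2"))
    }
    for (grp in config$hierarchy) {
      q1_grp <- pool[pool$quartile == 1 & pool$core_group == grp, ]
      if (nrow(q1_grp)) return(c(q1_grp$category_id[1], "hierarchy"))
    }
    stop("no quartile-1 or quartile-2 substitution candidate for ", src,
         " (degenerate dataset)", call. = FALSE)
  }

  res <- vapply(sources, pick, character(2))
  structure(tibble::tibble(source = sources,
                           target = unname(res[1, ]),
                           rule = unname(res[2, ])),
            class = c("substitution_map", class(tibble::tibble())))
}

#' Apply a substitution map to a diet
#'
#' Servings are transferred from each source category to its target:
#' one-for-one for core sources, while discretionary servings (150 kcal
#' each) convert into target servings of equal energy. The healthier diet
#' therefore contains zero discretionary servings, and its energy,
#' nutrients, cost and weight are recomputed from the target categories'
#' mean compositions.
#'
#' @param diet A `diet_profile` (current diet).
#' @param map A `substitution_map` covering every diet category.
#' @param categories Ranked category tibble.
#' @param config A `diet_config`.
#' @return The healthier `diet_profile`.
#' @export
apply_substitution <- function(diet, map, categories, config) {
  src <- diet$servings
  tgt_idx <- match(src$category_id, map$source)
  if (anyNA(tgt_idx)) {
    stop("substitution map does not cover: ",
         paste(src$category_id[is.na(tgt_idx)], collapse = ", "),
         call. = FALSE)
  }
  target_id <- map$target[tgt_idx]
  trow <- categories[match(target_id, categories$category_id), ]
  tkcal <- serving_energy(trow$core_group, trow$discretionary,
                          trow$mean_energy_kcal_100g, config)
  moved <- ifelse(src$discretionary,
                  src$servings_day * config$discretionary_serving_kcal /
                    tkcal,
                  src$servings_day)
  new_servings <- tapply(moved, target_id, sum)

  ids <- names(new_servings)
  rows <- categories[match(ids, categories$category_id), ]
  ss <- unlist(config$serving_sizes_g)
  pseudo <- tibble::tibble(
    member_ref = "household", day_index = 1L,
    category_id = ids,
    grams = as.numeric(new_servings) * ss[rows$core_group],
    match_method = "substitution")
  build_profile(pseudo, categories, config)
}

#' Substitution audit table
#'
#' Joins a substitution map with the servings actually moved out of each
#' source category in a diet.
#'
#' @param map A `substitution_map`.
#' @param diet The current `diet_profile` the map was applied to.
#' @return Tibble: `source`, `target`, `rule`, `servings_day_moved`.
#' @export
substitution_audit <- function(map, diet) {
  dplyr::left_join(
    map,
    dplyr::select(diet$servings, source = "category_id",
                  servings_day_moved = "servings_day"),
    by = "source")
}
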